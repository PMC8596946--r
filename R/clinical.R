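# Clinical battery: SCAT symptom scoring (22 items rated 0-6, with somatic /
# cognitive / sleep / mood domain sums), Wilcoxon paired and two-sample tests
# (exact null distribution for small untied samples, normal approximation
# with mid-ranks and tie-corrected variance otherwise), Benjamini-Hochberg
# FDR control, and Spearman attrition checks.

#' SCAT symptom items and domain partition
#'
#' The 22 symptom items in canonical order with their domain assignment:
#' somatic (9), cognitive (6), sleep (3), mood (4).
#'
#' @return data.frame with `item` (name) and `domain`.
#' @export
symptom_items <- function() {
  data.frame(
    item = c("headache", "pressure in head", "neck pain", "nausea",
             "dizziness", "blurred vision", "balance problems",
             "sensitivity to light", "sensitivity to noise",
             "feeling slowed down", "feeling 'in a fog'", "don't feel right",
             "difficulty concentrating", "difficulty remembering",
             "confusion",
             "fatigue", "drowsiness", "trouble falling asleep",
             "more emotional", "irritability", "sadness", "nervous/anxious"),
    domain = rep(c("somatic", "cognitive", "sleep", "mood"), c(9L, 6L, 3L, 4L)),
    stringsAsFactors = FALSE
  )
}

#' Score a 22-item symptom rating set
#'
#' @param items numeric vector of 22 integer ratings (0-6) in the canonical
#'   [symptom_items()] order, or a matrix / data.frame with 22 columns (one
#'   row per assessment).
#' @return data.frame with `total_symptoms` (count of nonzero items),
#'   `total_severity` (sum of ratings, 0-132) and the four domain sums.
#' @export
score_symptoms <- function(items) {
  m <- as.matrix(items)
  if (is.vector(items) || (is.null(dim(items)) && length(items) == 22L))
    m <- matrix(as.numeric(items), nrow = 1L)
  if (ncol(m) != 22L) stop("expected 22 symptom items, got ", ncol(m))
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0) || any(m > 6))
    stop("ratings must be integers in 0-6")
  dom <- symptom_items()$domain
  data.frame(
    total_symptoms = rowSums(m > 0),
    total_severity = rowSums(m),
    somatic = rowSums(m[, dom == "somatic", drop = FALSE]),
    cognitive = rowSums(m[, dom == "cognitive", drop = FALSE]),
    sleep = rowSums(m[, dom == "sleep", drop = FALSE]),
    mood = rowSums(m[, dom == "mood", drop = FALSE])
  )
}

rank_ties <- function(x) {
  r <- rank(x)                       # mid-ranks
  tab <- table(x)
  list(rank = r, tie_correction = sum(tab^3 - tab))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; ranks of `|d|` use mid-ranks. For untied
#' samples with `n <= 25` the p-value comes from the exact signed-rank null
#' distribution; otherwise from the normal approximation with tie-corrected
#' variance. The z statistic is always the (continuity-uncorrected) normal
#' deviate of the signed-rank statistic.
#'
#' @param x,y equal-length numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` (y > x shifts W up) or
#'   `"less"`.
#' @return list with `z`, `p`, `statistic` (W+, rank sum of positive
#'   `y - x`), `n_used`, `exact`.
#' @export
wilcoxon_paired <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(z = 0, p = if (alternative == "two.sided") 1 else 0.5,
                statistic = 0, n_used = 0L, exact = TRUE))
  rt <- rank_ties(abs(d))
  W <- sum(rt$rank[d > 0])
  mu <- n * (n + 1) / 4
  v <- n * (n + 1) * (2 * n + 1) / 24 - rt$tie_correction / 48
  if (v <= 0)
    return(list(z = 0, p = if (alternative == "two.sided") 1 else 0.5,
                statistic = W, n_used = n, exact = FALSE))
  z <- (W - mu) / sqrt(v)
  exact <- rt$tie_correction == 0 && n <= 25L
  p <- if (exact) {
    switch(alternative,
           greater = psignrank(W - 1, n, lower.tail = FALSE),
           less = psignrank(W, n),
           two.sided = min(1, 2 * min(psignrank(W, n),
                                      psignrank(W - 1, n, lower.tail = FALSE))))
  } else {
    switch(alternative,
           greater = pnorm(z, lower.tail = FALSE),
           less = pnorm(z),
           two.sided = 2 * pnorm(-abs(z)))
  }
  list(z = z, p = p, statistic = W, n_used = n, exact = exact)
}

#' Wilcoxon rank-sum test for two samples
#'
#' Mid-ranks with tie-corrected variance; exact null distribution
#' (`pwilcox`) for untied samples with both groups `<= 25`, normal
#' approximation otherwise.
#'
#' @param x,y numeric vectors (each length >= 3 for the approximation to be
#'   meaningful).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return list with `z`, `p`, `statistic` (Mann-Whitney U of `x`),
#'   `exact`.
#' @export
wilcoxon_twosample <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  rt <- rank_ties(all_v)
  R1 <- sum(rt$rank[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  v <- n1 * n2 / 12 * ((N + 1) - rt$tie_correction / (N * (N - 1)))
  if (v <= 0)
    return(list(z = 0, p = if (alternative == "two.sided") 1 else 0.5,
                statistic = U, exact = FALSE))
  z <- (U - mu) / sqrt(v)
  exact <- rt$tie_correction == 0 && n1 <= 25L && n2 <= 25L
  p <- if (exact) {
    switch(alternative,
           greater = pwilcox(U - 1, n1, n2, lower.tail = FALSE),
           less = pwilcox(U, n1, n2),
           two.sided = min(1, 2 * min(pwilcox(U, n1, n2),
                                      pwilcox(U - 1, n1, n2, lower.tail = FALSE))))
  } else {
    switch(alternative,
           greater = pnorm(z, lower.tail = FALSE),
           less = pnorm(z),
           two.sided = 2 * pnorm(-abs(z)))
  }
  list(z = z, p = p, statistic = U, exact = exact)
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up procedure at level `q`: reject the `k` smallest p-values where `k`
#' is the largest index with `p_(k) <= k q / m`.
#'
#' @param pvals p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return list with `reject` (logical, original order) and `p_adj`
#'   (BH-adjusted p-values).
#' @export
fdr_adjust <- function(pvals, q = 0.05) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  p_adj <- p.adjust(pvals, method = "BH")
  list(reject = p_adj <= q, p_adj = p_adj)
}

#' Attrition check: is session retention related to subject variables?
#'
#' Spearman correlation of each retention indicator (subject retained at a
#' session, 0/1) against each candidate variable, with Benjamini-Hochberg
#' FDR across all (session, variable) tests. Constant variables or
#' indicators give `NA` rho and are excluded from the FDR family.
#'
#' @param retained logical/0-1 matrix, subjects x sessions.
#' @param variables data.frame of numeric subject variables (same row
#'   order).
#' @param q FDR level.
#' @return data.frame with `session`, `variable`, `rho`, `p`,
#'   `fdr_significant`.
#' @export
attrition_check <- function(retained, variables, q = 0.05) {
  retained <- as.matrix(retained) * 1
  if (nrow(retained) < 10L) stop("attrition_check needs >= 10 subjects")
  stopifnot(nrow(retained) == nrow(variables))
  out <- list(); r <- 0L
  for (t in seq_len(ncol(retained))) {
    for (v in names(variables)) {
      r <- r + 1L
      x <- retained[, t]; y <- variables[[v]]
      ok <- is.finite(x) & is.finite(y)
      rho <- p <- NA_real_
      if (sum(ok) >= 5L && var(x[ok]) > 0 && var(y[ok]) > 0) {
        ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                               method = "spearman"))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      out[[r]] <- data.frame(
        session = colnames(retained)[t] %||% as.character(t),
        variable = v, rho = rho, p = p)
    }
  }
  tab <- do.call(rbind, out)
  tab$fdr_significant <- FALSE
  ok <- !is.na(tab$p)
  if (any(ok)) tab$fdr_significant[ok] <- fdr_adjust(pmax(tab$p[ok],
    .Machine$double.xmin), q)$reject
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clinical symptom test battery for a cohort
#'
#' Runs the nonparametric battery on a symptom table: per sex, paired
#' Wilcoxon tests of total symptoms and severity at ACU and RTP against
#' baseline (one-sided, elevation); male-female two-sample comparisons of
#' age, HOC rate, time to return to play, totals at each session, and the
#' four acute domain sums; all FDR-controlled at `q`.
#'
#' @param subjects subject table.
#' @param symptoms long table from [simulate_cohort()] (columns
#'   `subject_id`, `session`, `item_01`..`item_22`).
#' @param q FDR level.
#' @return data.frame with `comparison`, `z`, `p`, `fdr_significant`.
#' @export
clinical_report <- function(subjects, symptoms, q = 0.05) {
  item_cols <- grep("^item_", names(symptoms))
  sc <- cbind(symptoms[c("subject_id", "session")],
              score_symptoms(symptoms[, item_cols]))
  conc <- subjects[subjects$group == "concussed", ]
  get <- function(ids, session, col) {
    m <- sc[sc$session == session, ]
    m[[col]][match(ids, m$subject_id)]
  }
  rows <- list(); r <- 0L
  add <- function(name, res) {
    r <<- r + 1L
    rows[[r]] <<- data.frame(comparison = name, z = res$z, p = res$p)
  }
  for (sx in c(0, 1)) {
    ids <- conc$subject_id[conc$sex == sx]
    lab <- if (sx == 0) "male" else "female"
    for (col in c("total_symptoms", "total_severity")) {
      base <- get(ids, "baseline", col)
      for (sess in c("ACU", "RTP")) {
        v <- get(ids, sess, col)
        ok <- !is.na(base) & !is.na(v)
        add(sprintf("%s %s %s vs baseline", lab, col, sess),
            wilcoxon_paired(base[ok], v[ok], alternative = "greater"))
      }
    }
  }
  m_ids <- conc$subject_id[conc$sex == 0]
  f_ids <- conc$subject_id[conc$sex == 1]
  two <- function(name, xm, xf) {
    ok_m <- !is.na(xm); ok_f <- !is.na(xf)
    if (sum(ok_m) >= 3 && sum(ok_f) >= 3)
      add(name, wilcoxon_twosample(xf[ok_f], xm[ok_m]))
  }
  two("sex age", conc$age[conc$sex == 0], conc$age[conc$sex == 1])
  two("sex hoc", conc$hoc[conc$sex == 0], conc$hoc[conc$sex == 1])
  two("sex days_to_rtp", conc$days_to_rtp[conc$sex == 0],
      conc$days_to_rtp[conc$sex == 1])
  for (col in c("total_symptoms", "total_severity"))
    for (sess in c("baseline", "ACU", "RTP"))
      two(sprintf("sex %s %s", col, sess),
          get(m_ids, sess, col), get(f_ids, sess, col))
  for (col in c("somatic", "cognitive", "sleep", "mood"))
    two(sprintf("sex %s ACU", col), get(m_ids, "ACU", col),
        get(f_ids, "ACU", col))
  tab <- do.call(rbind, rows)
  tab$fdr_significant <- fdr_adjust(pmax(tab$p, .Machine$double.xmin), q)$reject
  tab
}
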