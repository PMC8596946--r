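# Repeated-measures bootstrap: athletes are resampled with replacement and
# each athlete's ACU/RTP/YR1 difference maps travel together as one
# resampling unit. Within each replicate the partially missing
# subject x (session, voxel) matrix is completed by SOFT-IMPUTE (fresh fit
# per replicate, threshold fixed at the cross-validated value), the summary
# matrix is rebuilt, the uncentered PLS refit, and the component sign-aligned
# to the reference fit. Bootstrap ratios are bootstrap mean / bootstrap SE,
# referred to the standard normal.

#' Sign-align a PLS component to a reference
#'
#' Multiplies the candidate's voxel and session saliences jointly by the sign
#' of the inner product between the reference and candidate voxel saliences
#' (+1 when the inner product is zero).
#'
#' @param reference,candidate `pls_component` objects of equal dimension.
#' @return the aligned candidate.
#' @export
align_component <- function(reference, candidate) {
  s <- sign(sum(reference$voxel_salience * candidate$voxel_salience))
  if (s == 0) s <- 1
  if (s < 0) {
    candidate$voxel_salience <- -candidate$voxel_salience
    candidate$session_salience <- -candidate$session_salience
  }
  candidate
}

# flatten a delta_set into the subject x (session, voxel) matrix used for
# imputation: column (t-1)*V + v holds session t, voxel v
flatten_deltas <- function(deltas) {
  n <- dim(deltas$delta)[1]; V <- dim(deltas$delta)[3]
  X <- matrix(NA_real_, n, 3L * V)
  for (t in 1:3)
    X[, ((t - 1L) * V + 1L):(t * V)] <- deltas$delta[, t, ]
  X
}

unflatten_summary <- function(X, type, sex = NULL) {
  V <- ncol(X) / 3L
  vals <- matrix(0, 3L, V, dimnames = list(SESSIONS, NULL))
  for (t in 1:3) {
    block <- X[, ((t - 1L) * V + 1L):(t * V), drop = FALSE]
    vals[t, ] <- if (type == "MEAN") colMeans(block) else colwise_cor(block, sex)
  }
  structure(list(values = vals, n_used = rep(nrow(X), 3L), type = type,
                 sessions = SESSIONS), class = "summary_matrix")
}

boot_stats <- function(sum_x, sum_x2, n) {
  m <- sum_x / n
  v <- pmax((sum_x2 - n * m^2) / (n - 1), 0)
  se <- sqrt(v)
  # an SE at floating-point rounding scale relative to the mean means the
  # statistic did not vary across replicates: signed-infinity sentinel
  degenerate <- se <= pmax(abs(m) * 1e-7, .Machine$double.xmin)
  bsr <- ifelse(degenerate, sign(m) * Inf, m / se)
  p <- ifelse(is.finite(bsr), 2 * pnorm(-abs(bsr)), 0)
  list(mean = m, se = se, bsr = bsr, p = p,
       n_degenerate = sum(degenerate & m != 0))
}

#' Repeated-measures bootstrap inference on PLS saliences
#'
#' @param deltas a `delta_set` ([difference_maps()]).
#' @param analysis `"MEAN"` (session-mean maps, concussion main effect) or
#'   `"SEXCORR"` (session-wise sex-correlation maps).
#' @param sex 0/1 per athlete (used for `SEXCORR`).
#' @param n_boot bootstrap iterations (default 1000; < 100 warns).
#' @param seed integer seed; results are deterministic given it.
#' @param lambda SOFT-IMPUTE threshold (numeric, or an `imputation_model`);
#'   required when any session is missing.
#' @param impute_tol,impute_max_rank forwarded to [soft_impute()]; the
#'   default replicate tolerance (1e-3) is looser than the final-fit default
#'   because per-replicate imputation error is dominated by resampling
#'   variability.
#' @return object of class `bootstrap_result`: the reference `component`,
#'   `voxel_bsr`, `session_bsr`, `voxel_p`, `session_p`, bootstrap means/SEs,
#'   `pct_cov` point estimate with percentile 95% CI, `n_boot`, `seed`,
#'   `n_degenerate`, `n_redrawn`.
#' @export
bootstrap_pls <- function(deltas, analysis = c("MEAN", "SEXCORR"),
                          sex = deltas$athletes$sex, n_boot = 1000L,
                          seed = 1L, lambda = NULL,
                          impute_tol = 1e-3, impute_max_rank = NULL) {
  analysis <- match.arg(analysis)
  if (n_boot < 100L) warning("n_boot < 100 gives unstable bootstrap ratios")
  summary0 <- if (analysis == "MEAN") session_mean_maps(deltas)
              else session_sex_correlation_maps(deltas, sex)
  ref <- uncentered_pls(summary0)

  X <- flatten_deltas(deltas)
  has_missing <- anyNA(X)
  if (has_missing) {
    if (inherits(lambda, "imputation_model")) lambda <- lambda$chosen_lambda
    if (is.null(lambda))
      stop("missing sessions present: supply lambda (or an imputation_model)")
    point_fit <- soft_impute(X, lambda, tol = impute_tol,
                             max_rank = impute_max_rank,
                             track_objective = FALSE)
    warm0 <- point_fit$Z
  } else warm0 <- NULL

  n <- nrow(X); V <- length(ref$voxel_salience)
  sv <- numeric(V); sv2 <- numeric(V)
  su <- numeric(3L); su2 <- numeric(3L)
  pct <- numeric(n_boot)
  n_redrawn <- 0L

  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) < 2L) { n_redrawn <- n_redrawn + 1L; next }
        if (analysis == "SEXCORR" &&
            (sum(sex[idx] == 0) < 2L || sum(sex[idx] == 1) < 2L)) {
          n_redrawn <- n_redrawn + 1L; next
        }
        break
      }
      Xb <- X[idx, , drop = FALSE]
      if (anyNA(Xb)) {
        fit <- soft_impute(Xb, lambda, tol = impute_tol,
                           max_rank = impute_max_rank,
                           warm = warm0[idx, , drop = FALSE],
                           track_objective = FALSE)
        Xb <- fit$completed
      }
      comp <- align_component(ref,
        uncentered_pls(unflatten_summary(Xb, analysis, sex[idx])))
      sv <- sv + comp$voxel_salience
      sv2 <- sv2 + comp$voxel_salience^2
      su <- su + comp$session_salience
      su2 <- su2 + comp$session_salience^2
      pct[b] <- comp$pct_covariance
    }
  })

  vs <- boot_stats(sv, sv2, n_boot)
  us <- boot_stats(su, su2, n_boot)
  ci <- unname(quantile(pct, c(0.025, 0.975)))
  structure(list(component = ref, analysis = analysis,
                 voxel_bsr = vs$bsr, voxel_p = vs$p,
                 voxel_boot_mean = vs$mean, voxel_boot_se = vs$se,
                 session_bsr = us$bsr, session_p = us$p,
                 session_boot_mean = us$mean, session_boot_se = us$se,
                 pct_cov = ref$pct_covariance, pct_cov_ci = ci,
                 pct_cov_boot = pct,
                 n_boot = n_boot, seed = seed,
                 n_degenerate = vs$n_degenerate + us$n_degenerate,
                 n_redrawn = n_redrawn),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result (%s): %d iterations, %% covariance %.1f [%.1f, %.1f]\n",
              x$analysis, x$n_boot, x$pct_cov, x$pct_cov_ci[1], x$pct_cov_ci[2]))
  cat("  session BSR:",
      paste(sprintf("%s=%.2f (p=%.3g)", SESSIONS, x$session_bsr, x$session_p),
            collapse = "  "), "\n")
  invisible(x)
}

roi_means <- function(deltas, roi_voxels) {
  n <- dim(deltas$delta)[1]
  R <- matrix(NA_real_, n, 3L, dimnames = list(rownames(deltas$available),
                                               SESSIONS))
  for (t in 1:3) {
    rows <- which(deltas$available[, t])
    R[rows, t] <- rowMeans(deltas$delta[rows, t, roi_voxels, drop = FALSE])
  }
  R
}

#' ROI effect statistics with repeated-measures bootstrap
#'
#' Averages the difference scores over a cluster of significant voxels and
#' reports, per group (all, male, female) and session: the mean, a bootstrap
#' percentile 95% CI, the bootstrap ratio, its normal p-value, and a
#' Benjamini-Hochberg FDR significance flag across the three sessions of each
#' group block. Also reports the female-minus-male contrast pooled over
#' `contrast_sessions`. Missing sessions are completed by SOFT-IMPUTE on the
#' athlete x session ROI-mean matrix (fresh fit per bootstrap replicate).
#'
#' @param deltas a `delta_set`.
#' @param roi_voxels integer in-mask column indices of the cluster.
#' @param sex 0/1 per athlete.
#' @param groups subset of `c("all", "male", "female")`.
#' @param n_boot bootstrap iterations.
#' @param seed integer seed.
#' @param lambda SOFT-IMPUTE threshold for the ROI matrix; when `NULL` and
#'   sessions are missing it is chosen by [select_lambda_cv()] on the ROI
#'   matrix.
#' @param contrast_sessions sessions pooled for the sex contrast (default all
#'   three).
#' @param q FDR level (default 0.05).
#' @return object of class `roi_stats`: `table` (group x session rows with
#'   mean, CI, BSR, p, fdr_significant) and `contrast` (female-male pooled
#'   mean, CI, BSR, p), plus bookkeeping fields.
#' @export
roi_statistics <- function(deltas, roi_voxels, sex = deltas$athletes$sex,
                           groups = c("all", "male", "female"),
                           n_boot = 1000L, seed = 1L, lambda = NULL,
                           contrast_sessions = SESSIONS, q = 0.05) {
  if (length(roi_voxels) == 0L) stop("empty ROI")
  R <- roi_means(deltas, roi_voxels)
  grp_rows <- list(all = seq_along(sex), male = which(sex == 0),
                   female = which(sex == 1))[groups]
  if (any(lengths(grp_rows) == 0L))
    stop("empty group: ", paste(groups[lengths(grp_rows) == 0L], collapse = ", "))
  has_missing <- anyNA(R)
  if (has_missing && is.null(lambda)) {
    lambda <- select_lambda_cv(R, seed = seed)$chosen_lambda
  }
  if (inherits(lambda, "imputation_model")) lambda <- lambda$chosen_lambda
  impute <- function(M) {
    if (!anyNA(M)) return(M)
    soft_impute(M, lambda, track_objective = FALSE)$completed
  }
  tcols <- match(contrast_sessions, SESSIONS)

  both_sexes <- any(sex == 0) && any(sex == 1)
  R0 <- impute(R)
  point <- lapply(grp_rows, function(rws) colMeans(R0[rws, , drop = FALSE]))
  point_contrast <- if (both_sexes)
    mean(R0[sex == 1, tcols]) - mean(R0[sex == 0, tcols]) else NA_real_

  nb <- n_boot
  gm <- lapply(grp_rows, function(.) matrix(NA_real_, nb, 3L))
  cvec <- numeric(nb)
  n <- nrow(R)
  with_seed(seed, {
    for (b in seq_len(nb)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) < 2L) next
        if (!both_sexes) break
        if (sum(sex[idx] == 0) >= 1L && sum(sex[idx] == 1) >= 1L) break
      }
      Rb <- impute(R[idx, , drop = FALSE])
      sb <- sex[idx]
      for (g in names(grp_rows)) {
        rws <- switch(g, all = seq_along(sb), male = which(sb == 0),
                      female = which(sb == 1))
        gm[[g]][b, ] <- colMeans(Rb[rws, , drop = FALSE])
      }
      cvec[b] <- if (both_sexes)
        mean(Rb[sb == 1, tcols]) - mean(Rb[sb == 0, tcols]) else NA_real_
    }
  })

  rows <- list(); r <- 0L
  for (g in names(grp_rows)) {
    m <- point[[g]]
    bm <- colMeans(gm[[g]])
    bse <- apply(gm[[g]], 2L, sd)
    bsr <- ifelse(bse > 0, bm / bse, sign(bm) * Inf)
    p <- ifelse(is.finite(bsr), 2 * pnorm(-abs(bsr)), 0)
    sig <- fdr_adjust(pmax(p, .Machine$double.xmin), q)$reject
    for (t in 1:3) {
      r <- r + 1L
      rows[[r]] <- data.frame(group = g, session = SESSIONS[t],
        mean = m[t], ci_lo = quantile(gm[[g]][, t], 0.025),
        ci_hi = quantile(gm[[g]][, t], 0.975), bsr = bsr[t], p = p[t],
        fdr_significant = sig[t])
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  contrast <- if (both_sexes) {
    cse <- sd(cvec)
    cbsr <- if (cse > 0) mean(cvec) / cse else sign(mean(cvec)) * Inf
    data.frame(
      mean = point_contrast,
      ci_lo = unname(quantile(cvec, 0.025)), ci_hi = unname(quantile(cvec, 0.975)),
      bsr = cbsr, p = if (is.finite(cbsr)) 2 * pnorm(-abs(cbsr)) else 0,
      sessions = paste(contrast_sessions, collapse = "+"))
  } else {
    data.frame(mean = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
               bsr = NA_real_, p = NA_real_,
               sessions = paste(contrast_sessions, collapse = "+"))
  }
  structure(list(table = tab, contrast = contrast, roi_size = length(roi_voxels),
                 n_boot = n_boot, seed = seed, lambda = lambda),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("roi_stats over %d voxels (%d bootstrap iterations)\n",
              x$roi_size, x$n_boot))
  print(x$table, digits = 3)
  cat("female - male contrast:\n")
  print(x$contrast, digits = 3)
  invisible(x)
}
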