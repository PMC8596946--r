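# Scan quality control: (1) univariate intensity QC comparing each scan's
# in-mask mean, variance and skew against the control distribution with
# Bonferroni-adjusted normal Z-tests; (2) a multivariate screen projecting
# maps onto the principal components of the control set (90% variance),
# standardizing scores by median/MAD, and flagging large robust distances
# against a chi-square reference with Bonferroni adjustment.

# adjusted Fisher-Pearson sample skewness
sample_skew <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / n)
  g1 <- sum((x - m)^3) / n / s^3
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

intensity_metrics <- function(v) {
  c(mean = mean(v), variance = var(v), skew = sample_skew(v))
}

#' Univariate intensity QC against the control distribution
#'
#' Computes the mean, variance and skew of a scan's in-mask intensities,
#' Z-scores each against the control scans' distribution of the same metric,
#' and flags the scan when any two-sided normal p-value falls below
#' `alpha / n_tests` (Bonferroni).
#'
#' @param values numeric vector (the scan's in-mask voxel values).
#' @param control_values matrix of control scans (rows) x voxels.
#' @param alpha nominal level (default 0.05).
#' @param n_tests number of tests the Bonferroni correction spans (default 3,
#'   the three metrics).
#' @param subject_id label carried into the result.
#' @return one-row data.frame: metrics, Z-scores, `flagged`.
#' @export
intensity_qc <- function(values, control_values, alpha = 0.05, n_tests = 3L,
                         subject_id = NA_character_) {
  if (nrow(control_values) < 3L) stop("intensity_qc needs >= 3 controls")
  stats <- intensity_metrics(values)
  ctrl <- t(apply(control_values, 1L, intensity_metrics))
  mu <- colMeans(ctrl)
  sdv <- apply(ctrl, 2L, sd)
  if (any(sdv == 0))
    stop("zero control SD for metric(s): ",
         paste(names(sdv)[sdv == 0], collapse = ", "))
  z <- (stats - mu) / sdv
  p <- 2 * pnorm(-abs(z))
  data.frame(subject_id = subject_id,
             mean = stats[1], variance = stats[2], skew = stats[3],
             z_mean = z[1], z_variance = z[2], z_skew = z[3],
             flagged = any(p < alpha / n_tests), row.names = NULL)
}

#' QC a whole map set against its controls
#'
#' Runs [intensity_qc()] for every map, using the control-session maps as the
#' reference distribution.
#'
#' @param maps a `map_set` (single modality).
#' @param alpha,n_tests see [intensity_qc()].
#' @return data.frame, one row per map (`subject_id`, `session`, metrics,
#'   Z-scores, `flagged`).
#' @export
qc_report <- function(maps, alpha = 0.05, n_tests = 3L) {
  ctrl <- maps$values[maps$info$session == "CONTROL", , drop = FALSE]
  out <- lapply(seq_len(nrow(maps$values)), function(i)
    cbind(intensity_qc(maps$values[i, ], ctrl, alpha, n_tests,
                       maps$info$subject_id[i]),
          session = maps$info$session[i]))
  do.call(rbind, out)
}

#' Multivariate outlier screen on a stack of maps
#'
#' Projects all maps onto the principal components that explain
#' `var_explained` of the reference (control) maps' variance, standardizes
#' each score by the reference median and MAD, and computes a robust squared
#' distance (sum of squared standardized scores). Maps whose chi-square
#' upper-tail p (df = number of components) falls below `alpha / n`
#' (Bonferroni over the `n` maps tested) are flagged.
#'
#' @param maps numeric matrix, maps (rows) x voxels.
#' @param alpha nominal level (default 0.05).
#' @param var_explained variance fraction retained (default 0.90).
#' @param reference_rows rows defining the reference distribution (default
#'   all rows).
#' @return logical vector of flags (length `nrow(maps)`), with attributes
#'   `distance` (robust squared distances) and `df`.
#' @export
multivariate_outliers <- function(maps, alpha = 0.05, var_explained = 0.90,
                                  reference_rows = seq_len(nrow(maps))) {
  n <- nrow(maps)
  if (n < 5L) stop("multivariate_outliers needs >= 5 maps")
  ref <- maps[reference_rows, , drop = FALSE]
  pc <- prcomp(ref, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) == 0) {                    # identical maps: nothing to flag
    flags <- rep(FALSE, n)
    attr(flags, "distance") <- rep(0, n)
    attr(flags, "df") <- 0L
    return(flags)
  }
  k <- which(cumsum(ev) / sum(ev) >= var_explained)[1]
  k <- min(k, nrow(ref) - 1L, n - 1L)
  scores <- sweep(maps, 2L, pc$center, `-`) %*% pc$rotation[, seq_len(k), drop = FALSE]
  ref_scores <- scores[reference_rows, , drop = FALSE]
  med <- apply(ref_scores, 2L, median)
  s <- apply(ref_scores, 2L, mad)
  s[s == 0] <- .Machine$double.eps
  zs <- sweep(sweep(scores, 2L, med, `-`), 2L, s, `/`)
  d2 <- rowSums(zs^2)
  p <- pchisq(d2, df = k, lower.tail = FALSE)
  flags <- p < alpha / n
  attr(flags, "distance") <- d2
  attr(flags, "df") <- k
  flags
}
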