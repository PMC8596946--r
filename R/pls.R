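# Uncentered task PLS: the 3 x V summary matrix (session-mean or session-wise
# sex-correlation maps) is decomposed by SVD with no row or column centering.
# The leading singular triplet gives a voxel salience pattern, the session
# saliences expressing it, and the fraction of summed squared singular values
# ("% covariance") it explains.

#' Session-mean summary matrix
#'
#' One row per imaging session (ACU, RTP, YR1): the arithmetic mean of the
#' available athletes' difference maps at each voxel. Athletes missing a
#' session are omitted from that row only.
#'
#' @param deltas a `delta_set` from [difference_maps()].
#' @return object of class `summary_matrix`: `values` (3 x V), `n_used`
#'   (athletes per session), `type = "MEAN"`, `sessions`.
#' @export
session_mean_maps <- function(deltas) {
  n_used <- colSums(deltas$available)
  if (any(n_used < 2L))
    stop("each session needs >= 2 athletes with data (got ",
         paste(n_used, collapse = "/"), ")")
  V <- dim(deltas$delta)[3]
  vals <- matrix(0, 3L, V, dimnames = list(SESSIONS, NULL))
  for (t in 1:3) {
    rows <- which(deltas$available[, t])
    vals[t, ] <- colMeans(deltas$delta[rows, t, , drop = FALSE][, 1, ])
  }
  structure(list(values = vals, n_used = n_used, type = "MEAN",
                 sessions = SESSIONS), class = "summary_matrix")
}

# fast columnwise Pearson correlation of y against the columns of X
colwise_cor <- function(X, y) {
  n <- length(y)
  xc <- sweep(X, 2L, colMeans(X), `-`)
  yc <- y - mean(y)
  sx <- sqrt(colSums(xc^2))
  sy <- sqrt(sum(yc^2))
  r <- as.vector(crossprod(xc, yc)) / (sx * sy)
  r[sx == 0] <- 0          # zero-variance voxels: correlation defined as 0
  r
}

#' Session-wise sex-correlation summary matrix
#'
#' One row per session: the point-biserial (Pearson) correlation between the
#' athletes' difference scores and sex (0 = male, 1 = female) at each voxel,
#' over the athletes with data at that session. Voxels with zero variance get
#' correlation 0 by convention (counted in `n_degenerate`).
#'
#' @param deltas a `delta_set`.
#' @param sex optional 0/1 vector per athlete; defaults to
#'   `deltas$athletes$sex`.
#' @return `summary_matrix` with `type = "SEXCORR"`.
#' @export
session_sex_correlation_maps <- function(deltas, sex = deltas$athletes$sex) {
  V <- dim(deltas$delta)[3]
  vals <- matrix(0, 3L, V, dimnames = list(SESSIONS, NULL))
  n_used <- integer(3L)
  n_degenerate <- 0L
  for (t in 1:3) {
    rows <- which(deltas$available[, t])
    s <- sex[rows]
    if (sum(s == 0) < 2L || sum(s == 1) < 2L)
      stop("session ", SESSIONS[t], " needs >= 2 athletes of each sex")
    X <- deltas$delta[rows, t, , drop = FALSE][, 1, , drop = TRUE]
    vals[t, ] <- colwise_cor(X, s)
    n_degenerate <- n_degenerate + sum(apply(X, 2, function(v) all(v == v[1])))
    n_used[t] <- length(rows)
  }
  structure(list(values = vals, n_used = n_used, type = "SEXCORR",
                 sessions = SESSIONS, n_degenerate = n_degenerate),
            class = "summary_matrix")
}

# SVD of a short-fat matrix via the small-side eigendecomposition; much
# faster than LAPACK's full bidiagonalization for 3 x V or 61 x 3V inputs.
svd_wide <- function(X, rank = nrow(X)) {
  e <- eigen(tcrossprod(X), symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  r <- min(rank, sum(d > max(d[1], .Machine$double.eps) * 1e-12))
  r <- max(r, 1L)
  u <- e$vectors[, seq_len(r), drop = FALSE]
  v <- crossprod(X, u)
  v <- sweep(v, 2L, pmax(d[seq_len(r)], .Machine$double.xmin), `/`)
  list(d = d[seq_len(nrow(X))], u = u, v = v, rank = r)
}

#' Uncentered task PLS of a summary matrix
#'
#' Singular value decomposition of the 3 x V summary matrix with no centering
#' of rows or columns. The first component is the leading singular triplet;
#' `pct_covariance = 100 * s1^2 / sum(si^2)`. Sign convention: the session
#' salience element with the largest magnitude is made positive (applied
#' jointly to both saliences, leaving the fit unchanged).
#'
#' @param summary a `summary_matrix`.
#' @return object of class `pls_component`: `voxel_salience` (unit length V),
#'   `session_salience` (unit length 3), `singular_values` (3),
#'   `pct_covariance`, `type`, `sessions`.
#' @export
uncentered_pls <- function(summary) {
  X <- summary$values
  if (any(!is.finite(X))) stop("summary matrix contains non-finite values")
  if (all(X == 0)) stop("summary matrix is all zero")
  s <- svd_wide(X)
  u1 <- s$u[, 1L]
  v1 <- s$v[, 1L]
  flip <- sign(u1[which.max(abs(u1))])
  if (flip < 0) { u1 <- -u1; v1 <- -v1 }
  d2 <- s$d^2
  structure(list(voxel_salience = v1, session_salience = u1,
                 singular_values = s$d,
                 pct_covariance = 100 * d2[1L] / sum(d2),
                 type = summary$type, sessions = summary$sessions),
            class = "pls_component")
}

#' @export
print.pls_component <- function(x, ...) {
  cat(sprintf("pls_component (%s): %% covariance %.1f, session saliences %s\n",
              x$type, x$pct_covariance,
              paste(sprintf("%s=%.3f", x$sessions, x$session_salience),
                    collapse = " ")))
  invisible(x)
}
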