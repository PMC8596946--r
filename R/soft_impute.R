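# Low-rank matrix completion by iterative soft-thresholded SVD: repeat
# Z <- SVT_lambda(P_obs(X) + P_miss(Z)) until the relative Frobenius change
# falls below tol. Each sweep does not increase the objective
# 0.5 * ||P_obs(X - Z)||_F^2 + lambda * ||Z||_* . The soft threshold lambda
# is chosen by repeated random-holdout cross-validation.

# Soft-thresholded SVD reconstruction. Works on the small side: with
# A (n x p, n <= p) and G = A A^T = U D^2 U^T, the thresholded fit is
# Z = U_r diag((d - lambda)/d) U_r^T A, so the right singular vectors are
# never materialized.
svt <- function(M, lambda, max_rank = NULL) {
  wide <- nrow(M) <= ncol(M)
  A <- if (wide) M else t(M)
  e <- eigen(tcrossprod(A), symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  d_new <- pmax(d - lambda, 0)
  r <- sum(d_new > 0)
  if (!is.null(max_rank)) r <- min(r, max_rank)
  if (r == 0L) {
    return(list(Z = matrix(0, nrow(M), ncol(M)), d = d_new, rank = 0L))
  }
  u <- e$vectors[, seq_len(r), drop = FALSE]
  scl <- d_new[seq_len(r)] / pmax(d[seq_len(r)], .Machine$double.xmin)
  W <- u * rep(scl, each = nrow(u))
  Zs <- W %*% crossprod(u, A)
  if (!wide) Zs <- t(Zs)
  d_kept <- d_new
  if (r < sum(d_new > 0)) d_kept[-seq_len(r)] <- 0  # rank cap drops the tail
  list(Z = Zs, d = d_kept, rank = r)
}

#' SOFT-IMPUTE low-rank matrix completion
#'
#' Fills the missing entries of `X` with the corresponding entries of a
#' low-rank fit `Z` obtained by iterating soft-thresholded SVD on the
#' observed-entry-filled matrix. Observed entries are returned unchanged.
#'
#' @param X numeric matrix with `NA` marking missing entries; every row and
#'   column must have at least one observed entry.
#' @param lambda soft threshold on singular values (>= 0).
#' @param tol convergence threshold on the squared relative Frobenius change
#'   `||Z_new - Z_old||_F^2 / ||Z_old||_F^2` (the reference algorithm's
#'   criterion).
#' @param max_iter sweep cap; non-convergence gives a warning and the last
#'   iterate.
#' @param max_rank optional cap on the rank of `Z`.
#' @param warm optional warm-start matrix for `Z` (same dims).
#' @param track_objective record the objective
#'   `0.5 ||P_obs(X - Z)||_F^2 + lambda ||Z||_*` at every sweep (the trace
#'   is non-increasing); skipping it avoids materializing the dense fit each
#'   sweep in inner loops.
#' @return list of class `soft_impute_fit`: `completed` (X with missing
#'   entries filled from Z), `Z` (the low-rank fit), `d` (thresholded
#'   singular values), `rank`, `objective` (per-sweep trace, empty when not
#'   tracked), `iterations`, `converged`.
#' @export
soft_impute <- function(X, lambda, tol = 1e-5, max_iter = 500L,
                        max_rank = NULL, warm = NULL,
                        track_objective = TRUE) {
  stopifnot(is.matrix(X), lambda >= 0)
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0L)) stop("soft_impute: row with no observed entry")
  if (any(colSums(obs) == 0L)) stop("soft_impute: column with no observed entry")
  miss <- which(!obs)
  if (length(miss) == 0L && lambda == 0) {
    return(structure(list(completed = X, Z = X, d = NULL, rank = NULL,
                          objective = numeric(0), iterations = 0L,
                          converged = TRUE), class = "soft_impute_fit"))
  }
  has_warm <- !is.null(warm)
  if (!has_warm) warm <- matrix(0, 1L, 1L)
  res <- soft_impute_core(X, miss - 1L, lambda, tol, as.integer(max_iter),
                          as.integer(max_rank %||% 0L), warm, has_warm,
                          isTRUE(track_objective))
  if (!res$converged)
    warning("soft_impute did not converge in ", max_iter, " sweeps")
  structure(list(completed = res$completed, Z = res$Z, d = drop(res$d),
                 rank = res$rank, objective = as.numeric(res$objective),
                 iterations = res$iterations, converged = res$converged),
            class = "soft_impute_fit")
}

default_lambda_grid <- function(X, length_out = 15L) {
  X0 <- X
  X0[is.na(X0)] <- 0
  d_max <- sqrt(max(eigen(if (nrow(X0) <= ncol(X0)) tcrossprod(X0)
                          else crossprod(X0), symmetric = TRUE,
                          only.values = TRUE)$values))
  exp(seq(log(d_max * 0.95), log(d_max * 0.05), length.out = length_out))
}

#' Choose the SOFT-IMPUTE threshold by random-holdout cross-validation
#'
#' Repeats `n_iter` times: hide a random `holdout_frac` of the observed
#' entries (resampled until every row and column keeps at least one observed
#' entry), impute with each candidate `lambda` (warm-started along the
#' descending grid), and score the squared error on the hidden entries.
#' The chosen `lambda` minimizes the mean held-out error.
#'
#' @param X matrix with `NA` for missing entries.
#' @param lambda_grid candidate thresholds; default 15 log-spaced values
#'   bracketing the largest singular value of the zero-filled matrix.
#' @param n_iter number of holdout repeats (default 200).
#' @param holdout_frac fraction of observed entries hidden per repeat
#'   (default 0.05).
#' @param seed integer; the selection is deterministic given the seed.
#' @param tol,max_iter,max_rank passed to [soft_impute()]; the CV default
#'   `tol = 1e-3` is looser than the final-fit default since only the
#'   relative ordering of candidate thresholds matters here.
#' @return list of class `imputation_model`: `chosen_lambda`, `lambda_grid`,
#'   `cv_error` (mean held-out MSE per grid value), `n_iter`,
#'   `holdout_frac`, `seed`.
#' @export
select_lambda_cv <- function(X, lambda_grid = NULL, n_iter = 200L,
                             holdout_frac = 0.05, seed = 1L,
                             tol = 1e-3, max_iter = 500L, max_rank = NULL) {
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(X)
  if (length(lambda_grid) == 0L) stop("empty lambda grid")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  obs_idx <- which(!is.na(X))
  n_hide <- max(1L, round(holdout_frac * length(obs_idx)))
  err_sum <- numeric(length(lambda_grid))
  err_n <- 0L
  # NOTE: warm starts are shared only along the descending lambda path
  # *within* a repeat. Warm-starting across repeats would leak the held-out
  # entries (an early-stopped iterate remembers values it fitted when they
  # were observed), biasing the CV error toward small lambda.
  with_seed(seed, {
    for (rep in seq_len(n_iter)) {
      for (try in 1:100) {
        hide <- sample(obs_idx, n_hide)
        Xh <- X
        Xh[hide] <- NA
        ok <- all(rowSums(!is.na(Xh)) > 0L) && all(colSums(!is.na(Xh)) > 0L)
        if (ok) break
      }
      if (!ok) stop("could not draw a holdout leaving all rows/columns observed")
      truth <- X[hide]
      warm <- NULL
      for (g in seq_along(lambda_grid)) {
        fit <- soft_impute(Xh, lambda_grid[g], tol = tol, max_iter = max_iter,
                           max_rank = max_rank, warm = warm,
                           track_objective = FALSE)
        warm <- fit$Z
        err_sum[g] <- err_sum[g] + mean((fit$Z[hide] - truth)^2)
      }
      err_n <- err_n + 1L
    }
  })
  cv_error <- err_sum / err_n
  structure(list(chosen_lambda = lambda_grid[which.min(cv_error)],
                 lambda_grid = lambda_grid, cv_error = cv_error,
                 n_iter = n_iter, holdout_frac = holdout_frac, seed = seed),
            class = "imputation_model")
}

#' @export
print.imputation_model <- function(x, ...) {
  cat(sprintf("imputation_model: lambda = %.4g chosen from %d-point grid (%d CV repeats, %.0f%% holdout)\n",
              x$chosen_lambda, length(x$lambda_grid), x$n_iter,
              100 * x$holdout_frac))
  invisible(x)
}
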