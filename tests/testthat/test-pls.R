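summary_from <- function(values, type = "MEAN") {
  structure(list(values = values, n_used = rep(10L, 3), type = type,
                 sessions = c("ACU", "RTP", "YR1")),
            class = "summary_matrix")
}

test_that("session means omit missing athletes and match a naive loop", {
  set.seed(21)
  n <- 9; V <- 30
  delta <- array(rnorm(n * 3 * V), dim = c(n, 3, V))
  avail <- matrix(TRUE, n, 3)
  avail[4, 3] <- FALSE; avail[7, 1] <- FALSE
  delta[4, 3, ] <- NA; delta[7, 1, ] <- NA
  ds <- make_delta_set(delta, avail)
  sm <- session_mean_maps(ds)
  # naive double loop oracle
  for (t in 1:3) {
    expected <- rep(0, V)
    cnt <- 0
    for (i in 1:n) if (avail[i, t]) { expected <- expected + delta[i, t, ]; cnt <- cnt + 1 }
    expect_equal(sm$values[t, ], expected / cnt)
    expect_equal(unname(sm$n_used[t]), cnt)
  }
  # two athletes v and -v average to zero
  d2 <- array(0, dim = c(2, 3, V))
  v <- rnorm(V); d2[1, 1, ] <- v; d2[2, 1, ] <- -v
  expect_equal(session_mean_maps(make_delta_set(d2))$values[1, ], rep(0, V))
})

test_that("sex-correlation maps are point-biserial with degenerate-voxel convention", {
  n <- 12; V <- 20
  sex <- rep(c(0, 1), each = 6)
  delta <- array(rnorm(n * 3 * V), dim = c(n, 3, V))
  # voxel 1: perfect separation a (males) vs b (females) -> r = sign(b - a)
  delta[, 1, 1] <- ifelse(sex == 1, 2, -1)
  # voxel 2: constant -> 0 by convention
  delta[, 1, 2] <- 5
  ds <- make_delta_set(delta, sex = sex)
  sm <- session_sex_correlation_maps(ds)
  expect_equal(unname(sm$values[1, 1]), 1)
  expect_equal(unname(sm$values[1, 2]), 0)
  expect_equal(sm$type, "SEXCORR")
  # oracle: cor() on a non-degenerate voxel
  expect_equal(unname(sm$values[2, 5]), cor(delta[, 2, 5], sex))
  expect_true(all(abs(sm$values) <= 1))
  # single-sex session errors
  expect_error(session_sex_correlation_maps(make_delta_set(delta,
    sex = rep(0, n))), "each sex")
})

test_that("uncentered PLS: rank-1 structure is recovered exactly", {
  V <- 50
  r <- rnorm(V)
  m <- rbind(r, 0, 0)
  comp <- uncentered_pls(summary_from(m))
  expect_equal(abs(comp$session_salience), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(comp$pct_covariance, 100)
  expect_equal(abs(cor(comp$voxel_salience, r)), 1, tolerance = 1e-12)
  # equal rows -> symmetric session salience
  m2 <- rbind(r, r, r)
  comp2 <- uncentered_pls(summary_from(m2))
  expect_equal(comp2$session_salience, rep(1, 3) / sqrt(3), tolerance = 1e-12)
  expect_equal(comp2$pct_covariance, 100)
  expect_error(uncentered_pls(summary_from(matrix(0, 3, V))), "zero")
})

test_that("uncentered PLS matches a dense SVD oracle on random matrices", {
  set.seed(33)
  for (i in 1:20) {
    m <- matrix(rnorm(3 * 200), 3, 200)
    comp <- uncentered_pls(summary_from(m))
    s <- svd(m)   # oracle: LAPACK SVD of the uncentered matrix
    expect_equal(comp$singular_values, s$d, tolerance = 1e-10)
    expect_equal(abs(comp$session_salience), abs(s$u[, 1]), tolerance = 1e-10)
    expect_equal(abs(comp$voxel_salience), abs(s$v[, 1]), tolerance = 1e-10)
    expect_equal(comp$pct_covariance, 100 * s$d[1]^2 / sum(s$d^2),
                 tolerance = 1e-10)
    # sign convention: largest-magnitude session salience positive
    expect_gt(comp$session_salience[which.max(abs(comp$session_salience))], 0)
    # unit norms
    expect_equal(sum(comp$voxel_salience^2), 1, tolerance = 1e-12)
    expect_equal(sum(comp$session_salience^2), 1, tolerance = 1e-12)
  }
})

test_that("pct covariance is invariant to voxel permutation and sign flips", {
  set.seed(34)
  m <- matrix(rnorm(3 * 100), 3, 100)
  base <- uncentered_pls(summary_from(m))$pct_covariance
  perm <- sample(100)
  expect_equal(uncentered_pls(summary_from(m[, perm]))$pct_covariance, base)
  expect_equal(uncentered_pls(summary_from(-m))$pct_covariance, base)
})

test_that("SVD reconstruction recovers the summary matrix", {
  set.seed(35)
  m <- matrix(rnorm(3 * 80), 3, 80)
  s <- normpls:::svd_wide(m)
  recon <- s$u %*% (s$d[seq_len(s$rank)] * t(s$v))
  expect_lt(max(abs(recon - m)), 1e-8)
})
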