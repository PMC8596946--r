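test_that("control matching applies sex, HOC and inclusive age-gap rules", {
  controls <- data.frame(
    subject_id = sprintf("C%d", 1:6),
    sex = c(1, 1, 1, 0, 1, 1),
    hoc = c(1, 1, 1, 1, 0, 1),
    age = c(18, 22.0, 22.01, 20, 20, 20))
  athlete <- list(subject_id = "P1", sex = 1, hoc = 1, age = 20)
  # exhaustive filter by hand: C1 (age 18, ok), C2 (22.0, inclusive), C6
  expect_identical(match_controls(athlete, controls), c("C1", "C2", "C6"))
  # 22.01 excluded (gap > 2), wrong sex / hoc excluded
  expect_false("C3" %in% match_controls(athlete, controls))
  expect_warning(
    match_controls(list(subject_id = "P2", sex = 0, hoc = 0, age = 99),
                   controls), "no controls matched")
})

test_that("huber_location: exact cases and equivariance", {
  expect_equal(huber_location(rep(3.7, 10)), 3.7)
  expect_equal(huber_location(c(-1, 0, 1)), 0, tolerance = 1e-10)
  # translation / scale equivariance
  x <- c(rnorm(20), 8, 9)
  m <- huber_location(x)
  expect_equal(huber_location(3 * x + 2), 3 * m + 2, tolerance = 1e-6)
  # k -> Inf recovers the arithmetic mean
  expect_equal(huber_location(c(1, 2, 3, 100), k = 1e6), mean(c(1, 2, 3, 100)),
               tolerance = 1e-8)
  expect_error(huber_location(numeric(0)), "finite")
})

test_that("huber_location agrees with direct minimization of the objective", {
  huber_rho <- function(u, k) ifelse(abs(u) <= k, u^2 / 2, k * abs(u) - k^2 / 2)
  oracle <- function(x, k = 1.35) {
    s <- 1.4826 * mad(x, constant = 1)
    if (s == 0) return(median(x))
    optimize(function(mu) sum(huber_rho((x - mu) / s, k)),
             range(x), tol = 1e-10)$minimum
  }
  set.seed(101)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    x <- rnorm(n)
    out <- rbinom(n, 1, 0.1) == 1
    x[out] <- x[out] + 10
    expect_equal(huber_location(x), oracle(x), tolerance = 1e-6)
  }
  # a single far outlier pulls the estimate only slightly past the bulk
  m <- huber_location(c(1, 2, 3, 100))
  expect_gt(m, 2); expect_lte(m, 3)
  expect_equal(m, oracle(c(1, 2, 3, 100)), tolerance = 1e-6)
})

test_that("huber_location cross-checks against an independent implementation", {
  set.seed(103)
  for (i in 1:10) {
    x <- c(rnorm(30), rnorm(3, 8))
    expect_equal(huber_location(x, k = 1.345),
                 unname(MASS::huber(x, k = 1.345)$mu), tolerance = 1e-4)
  }
})

test_that("one outlier moves the Huber mean less than the arithmetic mean", {
  x <- c(9.8, 10.1, 10.0, 9.9, 10.2)
  x_out <- c(x[-5], 60)
  shift_huber <- abs(huber_location(x_out) - huber_location(x))
  shift_mean <- abs(mean(x_out) - mean(x))
  expect_lt(shift_huber, shift_mean)
})

test_that("difference maps subtract the robust control mean per voxel", {
  cfg <- small_cohort_config(n_control = 80, n_concussed = 6, seed = 3)
  sim <- simulate_cohort(cfg)
  deltas <- difference_maps(sim$subjects, sim$maps)
  a1 <- deltas$athletes$subject_id[1]
  # recompute m for athlete 1 by scalar huber over matched control maps
  ids <- deltas$matched[[a1]]
  ctrl_rows <- which(sim$maps$info$subject_id %in% ids &
                       sim$maps$info$session == "CONTROL")
  vsel <- c(1, 17, 101)
  for (v in vsel)
    expect_equal(deltas$m[1, v], huber_location(sim$maps$values[ctrl_rows, v]),
                 tolerance = 1e-8)
  # delta = x - m, and the matched subgroup is shared across sessions
  row_acu <- which(sim$maps$info$subject_id == a1 &
                     sim$maps$info$session == "ACU")
  expect_equal(deltas$delta[1, "ACU", ], sim$maps$values[row_acu, ] - deltas$m[1, ],
               ignore_attr = TRUE)
  expect_identical(deltas$matched[[a1]], deltas$matched[[a1]])
  # athlete equal to the robust mean -> delta 0 (constructed)
  expect_equal(max(abs(deltas$delta[1, "ACU", ] -
                         (sim$maps$values[row_acu, ] - deltas$m[1, ]))), 0)
})

test_that("robust mean resists a gross outlier control map", {
  set.seed(5)
  n_ctrl <- 29; V <- 40    # typical matched-subgroup size
  ctrl <- matrix(rnorm(n_ctrl * V, 50, 2), n_ctrl, V)
  clean <- huber_location_cols(ctrl)
  ctrl_out <- rbind(ctrl, rep(500, V))
  robust <- huber_location_cols(ctrl_out)
  naive <- colMeans(ctrl_out)
  # recomputing without the outlier: the Huber mean moves < 0.1 noise SD
  # (the outlier's influence is capped at k * scale / n)
  expect_lt(max(abs(robust - clean)), 0.1 * 2)
  expect_gt(min(abs(naive - clean)), 1)
})
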