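test_that("smooth field: white-noise limit, determinism, negative fwhm", {
  f0 <- smooth_gaussian_field(c(10, 10, 10), 3, fwhm = 0, n = 4, seed = 1)
  expect_equal(mean(apply(f0, 2, var)), 1, tolerance = 0.1)
  f1 <- smooth_gaussian_field(c(8, 8, 8), 3, fwhm = 6, n = 2, seed = 9)
  f2 <- smooth_gaussian_field(c(8, 8, 8), 3, fwhm = 6, n = 2, seed = 9)
  expect_identical(f1, f2)
  expect_error(smooth_gaussian_field(c(8, 8, 8), 3, fwhm = -1), ">= 0")
})

test_that("smoothed-field lag-1 autocorrelation matches the Gaussian closed form", {
  # white noise * Gaussian kernel (sd sigma) has autocorrelation
  # exp(-d^2 / (4 sigma^2)) at lag d
  dims <- c(20, 20, 20); vox <- 3; fwhm <- 6
  sigma <- fwhm / sqrt(8 * log(2))
  expected <- exp(-vox^2 / (4 * sigma^2))
  f <- smooth_gaussian_field(dims, vox, fwhm, n = 30, seed = 13)
  a <- array(f[, 1], dims)
  lag1 <- function(x) {
    v <- array(x, dims)
    cor(as.vector(v[-dims[1], , ]), as.vector(v[-1, , ]))
  }
  obs <- mean(apply(f, 2, lag1))
  expect_lt(abs(obs - expected), 0.05)
  # unit variance preserved after smoothing renormalization
  expect_equal(mean(apply(f, 2, var)), 1, tolerance = 0.1)
})

test_that("cohort simulation is reproducible and honors dropout rates", {
  cfg <- small_cohort_config(seed = 23,
    dropout_probs = c(ACU = 8 / 61, RTP = 10 / 61, YR1 = 29 / 61))
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$maps$values, s2$maps$values)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$symptoms, s2$symptoms)

  # expected retention over many concussed athletes ~ 53/51/32 out of 61
  cfg2 <- sim_config(n_control = 5, n_concussed = 2000,
                     geometry = default_mask(c(6, 6, 6), 3),
                     modalities = "CBF",
                     main_effect = list(n_voxels = 0,
                       amplitudes = c(ACU = 0, RTP = 0, YR1 = 0)),
                     sex_effect = list(n_voxels = 0,
                       amplitudes = c(ACU = 0, RTP = 0, YR1 = 0)),
                     seed = 29)
  s3 <- simulate_cohort(cfg2)
  retained <- colMeans(s3$truth$retained) * 61
  expect_equal(unname(retained), c(53, 51, 32), tolerance = 0.04)
})

test_that("planted amplitudes are recovered by brute-force group means", {
  # large-n oracle: sample mean difference in the effect regions
  cfg <- sim_config(n_control = 400, n_concussed = 800,
                    geometry = default_mask(c(8, 8, 8), 3),
                    modalities = "CBF",
                    main_effect = list(n_voxels = 20,
                      amplitudes = c(ACU = -0.5, RTP = -0.7, YR1 = -1.0)),
                    sex_effect = list(n_voxels = 20,
                      amplitudes = c(ACU = 0.4, RTP = 0.8, YR1 = 0.6)),
                    dropout_probs = c(ACU = 0, RTP = 0, YR1 = 0),
                    seed = 31)
  sim <- simulate_cohort(cfg)
  tr <- truth_report(sim$truth)
  info <- sim$maps$info
  vals <- sim$maps$values
  sub <- sim$subjects
  noise_sd <- cfg$modality_params$CBF$noise_sd
  ctrl_rows <- which(info$session == "CONTROL")
  ctrl_sex <- sub$sex[match(info$subject_id[ctrl_rows], sub$subject_id)]
  # per-group SE of a region mean, inflated for covariate imbalance
  tol_se <- function(n1, n2) 3 * noise_sd * sqrt(1 / n1 + 1 / n2) + 0.3
  for (t in c("ACU", "RTP", "YR1")) {
    rows_t <- which(info$session == t)
    # main effect: concussed minus control group means in the main region
    # (covariates balance between groups at this n)
    main_vox <- sim$truth$main_region
    diff_obs <- mean(vals[rows_t, main_vox]) - mean(vals[ctrl_rows, main_vox])
    truth_val <- tr$true_contrast[tr$region == "main" & tr$session == t]
    expect_lt(abs(diff_obs - truth_val),
              tol_se(length(rows_t), length(ctrl_rows)))
    # sex-by-group effect: difference-in-differences removes the baseline
    # sex offset, leaving the planted amplitude
    sex_vox <- sim$truth$sex_region
    sexes <- sub$sex[match(info$subject_id[rows_t], sub$subject_id)]
    fm_conc <- mean(vals[rows_t[sexes == 1], sex_vox]) -
      mean(vals[rows_t[sexes == 0], sex_vox])
    fm_ctrl <- mean(vals[ctrl_rows[ctrl_sex == 1], sex_vox]) -
      mean(vals[ctrl_rows[ctrl_sex == 0], sex_vox])
    truth_sex <- tr$true_contrast[tr$region == "sex" & tr$session == t]
    expect_lt(abs((fm_conc - fm_ctrl) - truth_sex), 2 * tol_se(400, 400))
  }
})

test_that("null config: regions empty, truth contrasts zero", {
  cfg <- small_cohort_config(seed = 37)
  sim <- simulate_cohort(cfg)
  tr <- truth_report(sim$truth)
  expect_true(all(tr$true_contrast == 0))
  expect_equal(length(sim$truth$main_region), 0L)
})

test_that("written cohort directory matches what read_cohort expects", {
  tmp <- withr::local_tempdir()
  cfg <- small_cohort_config(n_control = 20, n_concussed = 3, seed = 39,
                             dims = c(8, 8, 8))
  sim <- simulate_cohort(cfg)
  paths <- write_cohort(sim, tmp)
  expect_true(file.exists(paths$manifest_path))
  man <- read.csv(paths$manifest_path)
  expect_setequal(names(man), normpls:::MANIFEST_COLS)
})
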