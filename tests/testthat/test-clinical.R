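test_that("symptom scoring: totals, domain partition, bounds", {
  z <- score_symptoms(rep(0L, 22))
  expect_equal(unlist(z), c(total_symptoms = 0, total_severity = 0,
                            somatic = 0, cognitive = 0, sleep = 0, mood = 0))
  s6 <- score_symptoms(rep(6L, 22))
  expect_equal(s6$total_severity, 132)
  expect_equal(s6$somatic, 54)     # 9 items x 6
  expect_equal(s6$cognitive, 36)   # 6 items x 6
  expect_equal(s6$sleep, 18)       # 3 items x 6
  expect_equal(s6$mood, 24)        # 4 items x 6
  # headache (item 1) is somatic
  v <- rep(0L, 22); v[1] <- 3L
  s <- score_symptoms(v)
  expect_equal(s$somatic, 3); expect_equal(s$cognitive, 0)
  expect_equal(s$total_symptoms, 1)
  expect_error(score_symptoms(c(rep(0L, 21), 7L)), "0-6")
  # domain sums always add to total severity
  set.seed(51)
  m <- matrix(sample(0:6, 22 * 20, replace = TRUE), 20, 22)
  sm <- score_symptoms(m)
  expect_equal(sm$somatic + sm$cognitive + sm$sleep + sm$mood,
               sm$total_severity)
  expect_equal(nrow(symptom_items()), 22L)
  expect_equal(unname(table(symptom_items()$domain)[c("somatic", "cognitive",
                                                      "sleep", "mood")]),
               c(9L, 6L, 3L, 4L), ignore_attr = TRUE)
})

test_that("paired Wilcoxon: edge cases and direction", {
  x <- rnorm(20)
  r <- wilcoxon_paired(x, x, alternative = "greater")
  expect_equal(r$z, 0); expect_equal(r$p, 0.5)   # one-sided convention
  expect_equal(wilcoxon_paired(x, x)$p, 1)
  up <- wilcoxon_paired(x, x + 10, alternative = "greater")
  expect_gt(up$z, 3.5)
  expect_lt(up$p, 0.001)
  dn <- wilcoxon_paired(x, x - 10, alternative = "greater")
  expect_gt(dn$p, 0.99)
})

test_that("paired Wilcoxon p matches exhaustive sign enumeration (n = 8)", {
  # oracle: enumerate all 2^n sign assignments of |d| ranks
  exact_paired <- function(d, alternative) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.vector(signs %*% r)
    switch(alternative,
           greater = mean(W_all >= W_obs),
           less = mean(W_all <= W_obs),
           two.sided = min(1, 2 * min(mean(W_all <= W_obs),
                                      mean(W_all >= W_obs))))
  }
  set.seed(52)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    x <- rnorm(n); y <- x + rnorm(n, 0.4)
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_paired(x, y, alt)
      expect_equal(got$p, exact_paired(y - x, alt), tolerance = 1e-12,
                   info = sprintf("n=%d alt=%s", n, alt))
    }
  }
})

test_that("two-sample Wilcoxon matches permutation enumeration (small n)", {
  exact_twosample <- function(x, y, alternative) {
    n1 <- length(x)
    all_v <- c(x, y)
    r <- rank(all_v)
    U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    cmb <- combn(length(all_v), n1)
    U_all <- apply(cmb, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    switch(alternative,
           greater = mean(U_all >= U_obs),
           less = mean(U_all <= U_obs),
           two.sided = min(1, 2 * min(mean(U_all <= U_obs),
                                      mean(U_all >= U_obs))))
  }
  set.seed(53)
  for (i in 1:6) {
    x <- rnorm(sample(4:7, 1)); y <- rnorm(sample(4:7, 1), 0.5)
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_twosample(x, y, alt)
      expect_equal(got$p, exact_twosample(x, y, alt), tolerance = 1e-12)
    }
  }
  # identical groups: z ~ 0; separated groups: extreme
  expect_lt(abs(wilcoxon_twosample(1:10, 1:10 + 0.5)$z), 1)
  sep <- wilcoxon_twosample(101:110, 1:10)
  expect_lt(sep$p, 0.001)
  expect_error(wilcoxon_twosample(numeric(0), 1:3), "empty")
})

test_that("BH step-up matches its definition and is monotone", {
  bh_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ok <- which(p[o] <= seq_len(m) * q / m)
    rej <- logical(m)
    if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
    rej
  }
  expect_false(any(fdr_adjust(rep(1, 5))$reject))
  expect_true(fdr_adjust(0.01)$reject)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04, 0.5))$reject,
               bh_oracle(c(0.01, 0.02, 0.04, 0.5), 0.05))
  set.seed(54)
  for (i in 1:300) {
    p <- runif(sample(3:12, 1))^sample(1:3, 1)
    expect_identical(fdr_adjust(p)$reject, bh_oracle(p, 0.05))
  }
  # monotonicity: lowering a p-value never loses rejections
  p <- c(0.011, 0.03, 0.2, 0.6)
  r1 <- fdr_adjust(p)$reject
  p2 <- p; p2[3] <- 0.012
  r2 <- fdr_adjust(p2)$reject
  expect_true(all(r2[r1]))
})

test_that("attrition check flags a planted association and handles constants", {
  set.seed(55)
  n <- 120
  vars <- data.frame(age = rnorm(n, 20, 2), sex = rbinom(n, 1, 0.5),
                     hoc = rbinom(n, 1, 0.5))
  retained <- cbind(ACU = runif(n) > 0.2,
                    RTP = vars$age > median(vars$age))  # perfect association
  res <- attrition_check(retained, vars)
  expect_true(res$fdr_significant[res$session == "RTP" & res$variable == "age"])
  # constant variable -> NA rho, no crash
  vars$const <- 1
  res2 <- attrition_check(retained, vars)
  expect_true(all(is.na(res2$rho[res2$variable == "const"])))
})

test_that("clinical battery reports acute elevation in a simulated cohort", {
  cfg <- small_cohort_config(n_control = 60, n_concussed = 40, seed = 17)
  sim <- simulate_cohort(cfg)
  rep <- clinical_report(sim$subjects, sim$symptoms)
  acu <- grepl("ACU vs baseline", rep$comparison)
  expect_true(all(rep$z[acu] > 0))
  expect_true(all(rep$fdr_significant[acu]))
  rtp <- grepl("severity RTP vs baseline", rep$comparison)
  expect_true(all(!rep$fdr_significant[rtp]))
})
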