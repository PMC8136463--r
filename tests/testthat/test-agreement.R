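test_that("bias and precision follow the mean/SD definitions", {
  bp <- bias_and_precision(c(2, -2))
  expect_equal(bp[["bias_mm"]], 0)
  expect_equal(bp[["precision_sd_mm"]], sqrt(8))  # n-1 denominator
  expect_equal(unname(bias_and_precision(rep(0, 5))), c(0, 0))
  set.seed(1)
  d <- rnorm(50)
  shifted <- bias_and_precision(d + 3)
  base <- bias_and_precision(d)
  expect_equal(shifted[["bias_mm"]], base[["bias_mm"]] + 3)
  expect_equal(shifted[["precision_sd_mm"]], base[["precision_sd_mm"]])
  expect_error(bias_and_precision(1), "at least 2")
})

test_that("absolute-deviation quantiles interpolate order statistics", {
  q <- abs_quantiles(c(-1, 2, -3, 4), probs = c(0.5, 1))
  expect_equal(unname(q), c(2.5, 4))
  expect_equal(unname(abs_quantiles(3, probs = c(0.1, 0.9))), c(3, 3))
  q2 <- abs_quantiles(c(1, -2, 3, -4, 5))
  expect_true(all(diff(q2) >= 0))      # nondecreasing in probability
  # linear-interpolation oracle, worked by hand: sorted |devs| 1 2 3 4,
  # p = 0.8 -> h = 1 + 0.8*3 = 3.4 -> 3 + 0.4*(4-3)
  expect_equal(unname(abs_quantiles(c(1, 2, 3, 4), probs = 0.8)), 3.4)
  expect_error(abs_quantiles(numeric(0)), "no deviations")
})

test_that("cumulative error curve is a nondecreasing CDF matching the quantiles", {
  cu <- cumulative_error_curve(c(1, 1, 1, 1))
  expect_equal(max(cu$fraction), 1)
  expect_true(all(cu$abs_dev_mm == 1))
  set.seed(2)
  d <- rnorm(31)
  cu2 <- cumulative_error_curve(d)
  expect_true(all(diff(cu2$fraction) >= 0))
  expect_true(all(diff(cu2$abs_dev_mm) >= 0))
  for (p in c(0.5, 0.8, 0.9)) {
    expect_equal(curve_quantile(cu2, p),
                 unname(abs_quantiles(d, probs = p)))
  }
})

test_that("ICC(2,1) matches an ANOVA mean-squares oracle", {
  m <- c(40, 42, 38, 45, 41, 39)
  r <- c(41, 41, 39, 44, 40, 40)
  res <- icc_absolute_agreement(cbind(m, r))

  # oracle: mean squares from aov() on the two-way layout, plugged into
  # the variance-component definition of absolute-agreement single-rater
  # ICC
  df <- data.frame(score = c(m, r),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(c("a", "b"), each = 6)))
  ms <- summary(aov(score ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  icc_oracle <- (MSR - MSE) / (MSR + MSE + 2 * (MSC - MSE) / 6)
  expect_equal(res$icc, icc_oracle)
  # independently cross-checked two-way random absolute-agreement value
  expect_equal(res$icc, 0.888060, tolerance = 1e-6)
  expect_equal(res$ci_low, 0.37, tolerance = 0.01)
  expect_equal(res$ci_high, 0.98, tolerance = 0.01)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
})

test_that("ICC limits: perfect agreement and noise-dominated data", {
  x <- c(35, 40, 45, 50, 55, 60)
  expect_equal(icc_absolute_agreement(cbind(x, x))$icc, 1.0)
  set.seed(3)
  noisy <- icc_absolute_agreement(
    cbind(x, x + rnorm(6, 0, 500)))
  expect_lt(abs(noisy$icc), 0.35)
  expect_error(icc_absolute_agreement(cbind(c(1, 1, 1), c(1, 1, 1))),
               "zero total variance")
  expect_error(icc_absolute_agreement(cbind(1:2, 2:3)), "3 complete")
})

test_that("ICC rises monotonically as measurement noise shrinks", {
  set.seed(9)
  truth <- rnorm(120, 47, 6.4)
  iccs <- vapply(c(8, 3, 0.5), function(s) {
    icc_absolute_agreement(cbind(truth + rnorm(120, 0, s), truth))$icc
  }, numeric(1))
  expect_true(all(diff(iccs) > 0))
})

test_that("variance-ratio test matches the F-distribution oracle", {
  x <- c(1.2, -0.5, 0.3, 2.2, -1.7, 0.9, 0.1, -0.8, 1.5, -0.2)
  same <- f_test_sd(x, x)
  expect_equal(same$statistic, 1)
  expect_equal(same$p_value, 1)

  set.seed(4)
  a <- rnorm(10, 0, 2); b <- rnorm(10, 0, 1)
  res <- f_test_sd(a, b)
  Fobs <- var(a) / var(b)
  p_oracle <- 2 * min(pf(Fobs, 9, 9), 1 - pf(Fobs, 9, 9))
  expect_equal(res$statistic, Fobs)
  expect_equal(res$p_value, p_oracle)

  sw <- f_test_sd(b, a)
  expect_equal(sw$statistic, 1 / res$statistic)
  expect_equal(sw$p_value, res$p_value)
  expect_error(f_test_sd(a, c(1, 1, 1)), "zero variance")
})

test_that("variance-ratio test holds its nominal type-I error", {
  set.seed(12)
  n_rep <- 2000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    rej[i] <- f_test_sd(rnorm(25), rnorm(25))$p_value < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("signed-rank test matches exact enumeration and is rank-invariant", {
  d <- c(0.4, 1.1, 0.7, 2.0, 0.2, 1.6)   # six all-positive differences
  res <- wilcoxon_abs_errors(d, rep(0, 6))
  expect_equal(res$statistic, 21)
  # oracle: enumerate all 2^6 sign assignments of ranks 1..6
  stats <- apply(expand.grid(rep(list(0:1), 6)), 1,
                 function(s) sum((1:6)[s == 1]))
  p_exact <- mean(abs(stats - 10.5) >= abs(21 - 10.5))
  expect_equal(res$p_value, p_exact)
  expect_equal(p_exact, 0.03125)

  scaled <- wilcoxon_abs_errors(7.3 * d, rep(0, 6))
  expect_equal(scaled$p_value, res$p_value)

  # antisymmetric differences sit at the null centre
  anti <- wilcoxon_abs_errors(c(1, 2, 3, 4) + c(0.5, -0.5, 0.5, -0.5),
                              c(1, 2, 3, 4))
  expect_gte(anti$p_value, 0.8)
  expect_error(wilcoxon_abs_errors(c(1, 2), c(1, 2)), "zero")
})

test_that("stratified summaries cover phases and flag thin strata", {
  set.seed(5)
  n <- 30
  dev <- do.call(rbind, lapply(c("ED", "ES"), function(ph) {
    ref <- rnorm(n, 47, 6)
    sdev <- rnorm(n, 0.5, if (ph == "ED") 1 else 2)
    data.frame(frame_id = sprintf("f_%s_%02d", ph, 1:n), method_id = "ai",
               phase = ph, dimension = "lvid", measurement_mm = ref + sdev,
               reference_mm = ref, signed_deviation_mm = sdev,
               stringsAsFactors = FALSE)
  }))
  s <- stratified_summaries(dev)
  expect_equal(nrow(s), 3)               # ED, ES, pooled
  pooled <- s[s$phase == "pooled", ]
  expect_equal(pooled$n, s$n[s$phase == "ED"] + s$n[s$phase == "ES"])
  expect_equal(pooled$bias_mm, mean(dev$signed_deviation_mm))
  expect_true(all(s$icc_ci_low <= s$icc & s$icc <= s$icc_ci_high))
  expect_true(all(c(s$q50_mm <= s$q80_mm, s$q80_mm <= s$q90_mm,
                    s$q90_mm <= s$q95_mm)))

  # a stratum with a single row is marked unavailable, not an error
  thin <- dev[1, ]
  thin$phase <- "ES"
  s2 <- stratified_summaries(rbind(dev[dev$phase == "ED", ], thin))
  expect_false(s2$available[s2$phase == "ES"])
  expect_true(is.na(s2$precision_sd_mm[s2$phase == "ES"]))
})
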