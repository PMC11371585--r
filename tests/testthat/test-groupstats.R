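test_that("per-ROI t-tests match the textbook pooled formula", {
  a <- matrix(c(55, 60, 58), 3, 1)
  b <- matrix(c(62, 65, 63), 3, 1)
  res <- roi_group_ttest(a, b, n_tests = 1)$table
  sp <- sqrt((2 * var(a[, 1]) + 2 * var(b[, 1])) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(2 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$p_raw, p_hand, tolerance = 1e-10)
  expect_identical(res$df, 4)
  expect_identical(res$direction, "lower_in_group1")
  # swapping groups negates t, preserves p
  rev_ <- roi_group_ttest(b, a, n_tests = 1)$table
  expect_equal(rev_$t_statistic, -res$t_statistic, tolerance = 1e-12)
  expect_equal(rev_$p_raw, res$p_raw, tolerance = 1e-12)
})

test_that("Bonferroni correction caps at 1 and controls the family-wise error", {
  set.seed(20)
  a <- matrix(rnorm(10 * 219, 60, 9), 10)
  b <- matrix(rnorm(10 * 219, 60, 9), 10)
  res <- roi_group_ttest(a, b)
  expect_true(all(res$table$p_bonferroni <= 1))
  expect_equal(res$table$p_bonferroni,
               pmin(1, res$table$p_raw * 219), tolerance = 1e-12)

  # null calibration: fraction of replicate cohorts with any flagged ROI
  effects <- list(group_effect_spec("control"),
                  group_effect_spec("tau_like"))
  hits <- vapply(1:100, function(r) {
    co <- generate_roi_cohort(c(control = 12, tau_like = 8), effects,
                              seed = 5000 + r)
    g <- co$manifest$group
    tt <- roi_group_ttest(co$roi_cbf[g == "tau_like", ],
                          co$roi_cbf[g == "control", ])
    any(tt$table$significant_fwe)
  }, logical(1))
  rate <- mean(hits)
  se <- sqrt(0.05 * 0.95 / 100)
  expect_lte(rate, 0.05 + 2 * se)
})

test_that("injected reductions at large effect size are all detected", {
  # 30% reduction of a 60 baseline with SD 9 gives Cohen's d = 2
  effects <- list(group_effect_spec("control"),
                  group_effect_spec("tdp_like", affected_rois = 11:15,
                                    cbf_reduction_fraction = 0.3))
  co <- generate_roi_cohort(c(control = 50, tdp_like = 14), effects,
                            roi_noise_sd = 9, seed = 31)
  g <- co$manifest$group
  tt <- roi_group_ttest(co$roi_cbf[g == "tdp_like", ],
                        co$roi_cbf[g == "control", ])
  flagged <- tt$table$parcel[tt$table$significant_fwe]
  expect_true(all(11:15 %in% flagged))
  expect_true(all(tt$table$direction[11:15] == "lower_in_group1"))
})

test_that("severity regression recovers exact and noisy slopes", {
  # noise-free: OLS is exact
  sev <- c(2, 4, 6, 8, 10, 12)
  y <- matrix(80 - 2 * sev, ncol = 1)
  fit <- severity_regression(y, sev)
  expect_equal(fit$slope, -2, tolerance = 1e-8)
  expect_equal(fit$intercept, 80, tolerance = 1e-8)

  # parameter recovery: mean recovered slope within 2 SE of the injected
  # value over 200 replicates at n = 14; null ROI flagged at ~5%
  slopes <- numeric(200)
  null_sig <- logical(200)
  for (r in 1:200) {
    set.seed(7000 + r)
    s <- runif(14, 1, 12)
    y2 <- cbind(70 - 2 * s + rnorm(14, 0, 5),   # injected slope -2
                60 + rnorm(14, 0, 5))           # null ROI
    f <- severity_regression(y2, s)
    slopes[r] <- f$slope[1]
    null_sig[r] <- f$significant_uncorrected[2]
  }
  se <- sd(slopes) / sqrt(200)
  expect_lt(abs(mean(slopes) - (-2)), 2 * se + 1e-9)
  expect_lt(abs(mean(null_sig) - 0.05), 0.05)
  expect_gt(mean(null_sig), 0.005)
})

test_that("severity regression rejects degenerate inputs", {
  y <- matrix(rnorm(10), ncol = 1)
  expect_error(severity_regression(y, rep(3, 10)), "variance")
  expect_error(severity_regression(y[1:2, , drop = FALSE], c(1, NA)),
               "at least 3")
  # participants without scores are dropped
  sev <- c(NA, NA, 1, 3, 5, 7, 9, 11, 13, 15)
  y2 <- matrix(50 - sev, ncol = 1)
  fit <- severity_regression(y2, sev)
  expect_identical(fit$n, 8L)
  expect_equal(fit$slope, -1, tolerance = 1e-8)
})

test_that("demographic comparisons use the pooled df and match chi-squared closed form", {
  set.seed(40)
  man <- data.frame(
    group = rep(c("tau_like", "tdp_like"), c(21, 14)),
    age = rnorm(35, 65, 8), education = rnorm(35, 15, 3),
    severity = runif(35, 1, 12),
    sex = sample(c("M", "F"), 35, replace = TRUE))
  res <- compare_demographics(man)
  ord <- res[res$test == "t", ]
  expect_true(all(ord$df == 33))  # 21 + 14 - 2

  # chi-squared on a hand-built 2x2 without continuity correction
  man2 <- data.frame(group = rep(c("tau_like", "tdp_like"), c(20, 20)),
                     sex = c(rep(c("M", "F"), c(12, 8)),
                             rep(c("M", "F"), c(6, 14))))
  got <- compare_demographics(man2)
  tab <- matrix(c(12, 8, 6, 14), 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  expect_equal(got$statistic[got$variable == "sex"], x2, tolerance = 1e-10)

  # identical groups: t = 0 and chi-squared p = 1
  manA <- data.frame(group = rep(c("tau_like", "tdp_like"), each = 6),
                     age = rep(c(60, 62, 64, 66, 68, 70), 2),
                     sex = rep(c("M", "M", "M", "F", "F", "F"), 2))
  same <- compare_demographics(manA)
  expect_equal(same$statistic[same$variable == "age"], 0, tolerance = 1e-12)
  expect_equal(same$p_value[same$variable == "sex"], 1, tolerance = 1e-12)
})
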