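# FRAP: double normalization, one-phase association fit, group statistics.

test_that("double normalization anchors pre-bleach mean at 1 and first post-bleach at 0", {
  cfg <- frap_sim_config(acquisition_bleach = 0.01, noise_sd = 0)
  tr <- simulate_frap_trace(cfg)
  nm <- double_normalize(tr)
  expect_equal(mean(nm$normalized[nm$prebleach_flag]), 1)
  expect_equal(nm$normalized[which(!nm$prebleach_flag)[1]], 0)
})

test_that("a flat trace is rejected as having no bleach event", {
  tr <- data.frame(time_s = seq(-3.6, 10, 0.9), roi = 1, reference = 1,
                   prebleach_flag = seq(-3.6, 10, 0.9) < 0)
  expect_error(double_normalize(tr), "no bleach detected")
  bad_ref <- data.frame(time_s = 0:5, roi = 1, reference = c(1, 1, 0, 1, 1, 1),
                        prebleach_flag = c(TRUE, rep(FALSE, 5)))
  expect_error(double_normalize(bad_ref), "non-positive reference")
})

test_that("normalized plateau equals the mobile fraction on noiseless traces", {
  for (mf in c(0.6, 1)) {
    cfg <- frap_sim_config(mobile_fraction = mf, noise_sd = 0,
                           acquisition_bleach = 0.002, n_frames = 80)
    fit <- frap_roundtrip(cfg)
    expect_lt(abs(fit$plateau - mf) / mf, 0.01)
    if (mf == 1) {
      # full recovery: asymptote equals the pre-bleach level
      nm <- double_normalize(simulate_frap_trace(cfg))
      expect_gt(max(nm$normalized[!nm$prebleach_flag]), 0.99)
    }
  }
})

test_that("fits recover the generating half-time exactly on noiseless traces", {
  # ln 2 / k identity at k = 0.0693/s
  cfg <- frap_sim_config(rate_k = 0.0693, noise_sd = 0)
  fit <- frap_roundtrip(cfg)
  expect_equal(fit$t_half, 10.0, tolerance = 1e-3)
  expect_equal(fit$t_half * fit$rate_k, log(2)) # exact identity
  # wild-type-scale recovery half-time round trip
  cfg2 <- frap_sim_config(rate_k = log(2) / 8.82, noise_sd = 0)
  fit2 <- frap_roundtrip(cfg2)
  expect_lt(abs(fit2$t_half - 8.82) / 8.82, 0.001)
})

test_that("fit is invariant to time shifts of the post-bleach origin and intensity rescaling", {
  cfg <- frap_sim_config(rate_k = 0.1, mobile_fraction = 0.8, noise_sd = 0)
  tr <- simulate_frap_trace(cfg)
  fit0 <- fit_one_phase(double_normalize(tr))
  shifted <- tr
  shifted$time_s <- shifted$time_s + 13.7
  fit_s <- fit_one_phase(double_normalize(shifted))
  expect_equal(fit_s$rate_k, fit0$rate_k, tolerance = 1e-8)
  scaled <- tr
  scaled$roi <- scaled$roi * 540
  scaled$reference <- scaled$reference * 540
  fit_g <- fit_one_phase(double_normalize(scaled))
  expect_equal(fit_g$rate_k, fit0$rate_k, tolerance = 1e-8)
})

test_that("noisy traces recover the half-time with small median error and bias", {
  k <- log(2) / 8.82
  errs <- vapply(1:50, function(s) {
    cfg <- frap_sim_config(rate_k = k, noise_sd = 0.05, seed = 1000 + s)
    fit <- frap_roundtrip(cfg)
    abs(fit$t_half - 8.82) / 8.82
  }, 0)
  expect_lt(median(errs), 0.05)
  ks <- vapply(1:30, function(s) {
    cfg <- frap_sim_config(rate_k = k, noise_sd = 0.02, seed = 2000 + s)
    frap_roundtrip(cfg)$rate_k
  }, 0)
  expect_lt(abs(mean(ks) - k) / k, 0.02) # bias under 2%
})

test_that("D'Agostino-Pearson statistic matches an independent reference implementation", {
  # frozen from scipy.stats.normaltest on the same fixtures
  set.seed(7)
  x <- rnorm(20, 5, 2)
  res <- dagostino_pearson_test(x)
  expect_equal(unname(res$statistic), 2.528945512118, tolerance = 1e-9)
  expect_equal(res$p.value, 0.282388144336, tolerance = 1e-9)
  set.seed(9)
  y <- rlnorm(25, 0, 1)
  res2 <- dagostino_pearson_test(y)
  expect_equal(unname(res2$statistic), 18.570778222309, tolerance = 1e-9)
  expect_equal(res2$p.value, 0.000092769827, tolerance = 1e-9)
  expect_error(dagostino_pearson_test(rnorm(5)), "n >= 8")
})

test_that("group comparison routes by normality and matches the closed-form t statistic", {
  set.seed(21)
  g1 <- rnorm(15, 8.82, 1)
  g2 <- rnorm(15, 4.48, 1)
  df <- data.frame(group = rep(c("wt", "mut"), each = 15), value = c(g1, g2))
  cmp <- compare_groups(df)
  expect_equal(cmp$test, "t test")
  expect_lt(cmp$p.value, 0.001)
  expect_equal(cmp$stars, "***")
  # closed-form pooled two-sample t as oracle
  sp2 <- ((15 - 1) * var(g1) + (15 - 1) * var(g2)) / 28
  tstat <- (mean(g1) - mean(g2)) / sqrt(sp2 * (2 / 15))
  p_oracle <- 2 * pt(abs(tstat), 28, lower.tail = FALSE)
  expect_equal(cmp$p.value, p_oracle, tolerance = 1e-12)
  expect_equal(abs(cmp$statistic), abs(tstat), tolerance = 1e-12)
  # identical groups: P ~ 1, no stars
  same <- data.frame(group = rep(c("a", "b"), each = 15),
                     value = rep(rnorm(15, 5, 1), 2))
  cmp_same <- compare_groups(same)
  expect_gt(cmp_same$p.value, 0.9)
  expect_equal(cmp_same$stars, "none")
})

test_that("skewed data are routed to rank-based tests, three groups to ANOVA/KW", {
  set.seed(31)
  df <- data.frame(group = rep(c("a", "b"), each = 30),
                   value = c(rlnorm(30, 0, 1.5), rnorm(30, 2, 0.5)))
  cmp <- compare_groups(df)
  expect_equal(cmp$test, "Mann-Whitney U test")
  set.seed(33)
  df3 <- data.frame(group = rep(c("a", "b", "c"), each = 15),
                    value = c(rnorm(15, 5), rnorm(15, 6), rnorm(15, 7)))
  expect_equal(compare_groups(df3)$test, "one-way ANOVA")
  set.seed(33)
  df3$value[1:15] <- rlnorm(15, 0, 1.6)
  expect_equal(compare_groups(df3)$test, "Kruskal-Wallis ANOVA")
  # small groups are excluded with a warning
  dfs <- rbind(df3, data.frame(group = "tiny", value = c(1, 2)))
  expect_warning(compare_groups(dfs), "n < 3")
})
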