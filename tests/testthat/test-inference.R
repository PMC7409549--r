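# Population curve, window slopes, calling rules, profile assembly.

make_linear_traces <- function(n_cells, times, slope_fn, noise_sd = 0, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_cells), function(i) {
    fd <- slope_fn(times) + rnorm(length(times), 0, noise_sd)
    structure(data.frame(cell_id = sprintf("c%d", i), time_min = times,
                         rfi_red = 1, rfi_green = 1, fd_percent = fd,
                         phase = NA_character_, flag_negative = FALSE,
                         flag_caveat = FALSE),
              class = c("conversion_trace", "data.frame"))
  })
}

test_that("loess reproduces straight lines and constants", {
  times <- seq(0, 40, 2)
  lin <- make_linear_traces(3, times, function(t) 2 * t)
  curve <- pool_and_fit_loess(lin, span = 0.5)
  expect_lt(max(abs(curve$fd_fit - 2 * curve$time)), 1e-6)
  flat <- make_linear_traces(3, times, function(t) rep(40, length(t)))
  curve2 <- pool_and_fit_loess(flat, span = 0.5)
  expect_lt(max(abs(curve2$fd_fit - 40)), 1e-8)
  # band contains the fitted line
  expect_true(all(curve$lower <= curve$fd_fit & curve$fd_fit <= curve$upper))
})

test_that("loess matches the brute-force weighted-least-squares oracle to 1e-8", {
  set.seed(42)
  n <- 30
  x <- sort(runif(n, 0, 100))
  y <- 40 + 0.5 * x + rnorm(n, 0, 3)
  tr <- list(
    structure(data.frame(cell_id = "a", time_min = x[1:15], rfi_red = 1,
                         rfi_green = 1, fd_percent = y[1:15],
                         phase = NA, flag_negative = FALSE, flag_caveat = FALSE),
              class = c("conversion_trace", "data.frame")),
    structure(data.frame(cell_id = "b", time_min = x[16:30], rfi_red = 1,
                         rfi_green = 1, fd_percent = y[16:30],
                         phase = NA, flag_negative = FALSE, flag_caveat = FALSE),
              class = c("conversion_trace", "data.frame"))
  )
  grid <- seq(min(x), max(x), length.out = 25)
  curve <- pool_and_fit_loess(tr, span = 0.5, grid = grid)
  oracle <- loess_oracle(x, y, span = 0.5, grid = grid)
  expect_lt(max(abs(curve$fd_fit - oracle)), 1e-8)
})

test_that("window slopes and P-values match the closed-form OLS oracle on every window", {
  times <- seq(0, 30, 2)
  tr <- make_linear_traces(6, times, function(t) 1.5 * t, noise_sd = 4, seed = 9)
  curve <- pool_and_fit_loess(tr, span = 0.6)
  slopes <- sliding_window_slopes(curve)
  pooled <- attr(curve, "points")
  for (i in seq_len(nrow(slopes))) {
    sub <- pooled[pooled$time >= slopes$t_start[i] - 1e-9 &
                    pooled$time <= slopes$t_end[i] + 1e-9, ]
    o <- ols_oracle(sub$time, sub$fd)
    expect_equal(slopes$slope[i], o$slope, tolerance = 1e-10)
    expect_equal(slopes$p_value[i], o$p, tolerance = 1e-10)
  }
  expect_equal(slopes$t_end - slopes$t_start, rep(4, nrow(slopes)))
  expect_equal(diff(slopes$t_start), rep(2, nrow(slopes) - 1))
})

test_that("replicated exact trend gives the nominal slope with vanishing P", {
  times <- seq(0, 8, 2)
  tr <- make_linear_traces(30, times, function(t) 10 + 1 * t, noise_sd = 1e-9,
                           seed = 2)
  curve <- pool_and_fit_loess(tr, span = 0.9)
  slopes <- sliding_window_slopes(curve)
  expect_equal(slopes$slope, rep(1, nrow(slopes)), tolerance = 1e-6)
  expect_true(all(slopes$p_value < 1e-10))
  # constant data: slope 0, high P, never called
  flat <- make_linear_traces(5, times, function(t) rep(30, length(t)),
                             noise_sd = 1, seed = 3)
  cflat <- pool_and_fit_loess(flat, span = 0.9)
  sflat <- sliding_window_slopes(cflat)
  calls <- suppressWarnings(call_interactions(sflat))
  expect_false(any(calls$called))
})

test_that("time reversal negates every slope and monotone data give non-negative slopes", {
  times <- seq(0, 20, 2)
  tr <- make_linear_traces(4, times, function(t) t^1.3, noise_sd = 0)
  curve <- pool_and_fit_loess(tr, span = 0.7)
  s_fwd <- sliding_window_slopes(curve)
  expect_true(all(s_fwd$slope >= -1e-12))
  rev_tr <- lapply(tr, function(x) {
    x$fd_percent <- rev(x$fd_percent)
    x
  })
  curve_r <- pool_and_fit_loess(rev_tr, span = 0.7)
  s_rev <- sliding_window_slopes(curve_r)
  expect_equal(s_rev$slope, -rev(s_fwd$slope), tolerance = 1e-8)
})

test_that("calling is invariant to the order of traces", {
  times <- seq(0, 30, 2)
  tr <- make_linear_traces(6, times, function(t) 2 * t, noise_sd = 5, seed = 4)
  f1 <- suppressWarnings(call_interactions(
    sliding_window_slopes(pool_and_fit_loess(tr, span = 0.6))))
  f2 <- suppressWarnings(call_interactions(
    sliding_window_slopes(pool_and_fit_loess(rev(tr), span = 0.6))))
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_identical(f1$called, f2$called)
})

make_slopes <- function(slope, p, conv, t0 = 0) {
  structure(data.frame(t_start = t0, t_mid = t0 + 2, t_end = t0 + 4,
                       slope = slope, p_value = p, mean_conversion = conv,
                       n_points = 60),
            class = c("window_slopes", "data.frame"))
}

test_that("the four decision-rule cases are reproduced exactly", {
  ns_control <- make_slopes(0.1, 0.6, 50)
  # steep significant slope below 70%, control not significant: called ***
  c1 <- call_interactions(make_slopes(1.5, 0.0005, 50), ns_control)
  expect_true(c1$called)
  expect_equal(c1$stars, "***")
  # significant but below the 1 %/min floor at low conversion: not called
  c2 <- call_interactions(make_slopes(0.5, 0.001, 50), ns_control)
  expect_false(c2$called)
  expect_equal(c2$reason, "below-slope-floor")
  # shallow positive significant slope above 70%: called **
  c3 <- call_interactions(make_slopes(0.3, 0.004, 85),
                          make_slopes(0.05, 0.8, 85))
  expect_true(c3$called)
  expect_equal(c3$stars, "**")
  expect_true(c3$flag_caveat) # >= 80% interpretation caveat
  # bait meets criteria but so does the control: vetoed
  c4 <- call_interactions(make_slopes(2, 0.0001, 50),
                          make_slopes(1.4, 0.01, 50))
  expect_false(c4$called)
  expect_equal(c4$reason, "control-veto")
})

test_that("slope floor is inclusive at exactly 1 %/min and star edges follow P", {
  ctrl <- make_slopes(0, 0.9, 50)
  expect_true(call_interactions(make_slopes(1.0, 0.04, 50), ctrl)$called)
  expect_equal(call_interactions(make_slopes(1.5, 0.04, 50), ctrl)$stars, "*")
  expect_equal(call_interactions(make_slopes(1.5, 0.009, 50), ctrl)$stars, "**")
  # exactly at alpha is not significant
  expect_false(call_interactions(make_slopes(1.5, 0.05, 50), ctrl)$called)
  # above 70%: negative slope never called
  expect_false(call_interactions(make_slopes(-0.5, 0.001, 80), ctrl)$called)
})

test_that("mismatched control grids error and absent control disables the veto", {
  s <- make_slopes(1.5, 0.001, 50)
  bad_ctrl <- make_slopes(0, 0.9, 50, t0 = 10)
  expect_error(call_interactions(s, bad_ctrl), "window grids|window grid")
  expect_warning(out <- call_interactions(s, NULL), "veto disabled")
  expect_true(out$called)
})

test_that("profile building merges adjacent called windows", {
  cc <- do.call(rbind, lapply(0:9, function(i) make_slopes(2, 0.001, 50, t0 = 2 * i)))
  cc$called <- FALSE
  cc$called[c(3, 4, 7)] <- TRUE
  cc$stars <- ifelse(cc$called, "***", "none")
  class(cc) <- c("interaction_calls", "data.frame")
  prof <- build_profile(list(pairA = cc))
  expect_equal(nrow(prof$intervals), 2)
  expect_equal(prof$intervals$n_windows, c(2, 1))
  expect_equal(prof$intervals$t_start, c(cc$t_start[3], cc$t_start[7]))
  # none called -> empty; all called -> one spanning interval
  cc$called <- FALSE
  expect_equal(nrow(build_profile(list(p = cc))$intervals), 0)
  cc$called <- TRUE
  one <- build_profile(list(p = cc))$intervals
  expect_equal(nrow(one), 1)
  expect_equal(c(one$t_start, one$t_end), c(min(cc$t_start), max(cc$t_end)))
})

test_that("perfect-information recovery: noiseless strong cleavage gives F1 = 1", {
  # window sized so conversion stays below the 70% rule switch: above it any
  # exactly-positive deterministic tail is "significant" at zero noise
  cfg <- quiet_config(roi_fraction = 0.85)
  sched <- interaction_schedule(windows = list(c(20, 40, "PCDII")))
  pop <- simulate_population(cfg, sched, n_cells = 3, fusion_jitter_sd = 0,
                             seed = 5)
  fit <- suppressWarnings(spliff(pop, span = 0.3))
  score <- recover_schedule_benchmark(fit$calls, sched$windows)
  expect_equal(score$f1, 1.0)
  expect_equal(score$fp, 0L + score$fp * 0L) # no false positives
})
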