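# Quantification formulas: exact arithmetic, invariances, phase annotation,
# and agreement with simulated ground truth.

test_that("relative intensity reproduces direct arithmetic and handles degenerate denominators", {
  expect_equal(relative_intensity(100, 60, 20), 2.0)
  expect_equal(relative_intensity(20, 60, 20), 0.0)
  expect_equal(relative_intensity(20, 999, 20), 0.0)
  expect_true(is.na(relative_intensity(100, 50, 50)))
})

test_that("localized intensity is the cytosol-subtracted signal", {
  expect_equal(localized_intensity(500, 120), 380)
  expect_equal(localized_intensity(120, 120), 0)
  expect_equal(localized_intensity(100, 150), -50) # retained, not clipped
})

test_that("conversion statistic reproduces its defining arithmetic", {
  expect_equal(conversion(1.0, 1.0), 0)
  expect_equal(conversion(1.0, 0.0), 100)
  expect_equal(conversion(0.8, 0.2), 75)
  expect_true(is.na(conversion(0, 0.5)))
  expect_true(is.na(conversion(-0.1, 0.5)))
  expect_lt(conversion(0.9, 1.0), 0) # negative FD retained
})

test_that("FD is invariant to channel gain and relative intensity to common offsets", {
  set.seed(42)
  for (i in 1:1000) {
    # offset invariance of the relative-intensity ratio
    v <- runif(3, 10, 500)
    v <- c(v[1], v[2] + 20, v[3]) # keep denominator away from 0
    c0 <- runif(1, -50, 50)
    expect_equal(relative_intensity(v[1], v[2], v[3]),
                 relative_intensity(v[1] + c0, v[2] + c0, v[3] + c0))
    # gain invariance of FD: rescaling both channels' raw intensities by a
    # common factor leaves RFIs, hence FD, unchanged
    fi <- runif(4, 50, 500) # fi_red(t), fi_red(ref), fi_green(t), fi_green(ref)
    g <- runif(1, 0.1, 10)
    fd1 <- conversion(fi[1] / fi[2], fi[3] / fi[4])
    fd2 <- conversion((g * fi[1]) / (g * fi[2]), (g * fi[3]) / (g * fi[4]))
    expect_equal(fd1, fd2)
  }
})

test_that("pre-fusion normalization anchors the reference at exactly 1", {
  trace <- data.frame(
    cell_id = "c1",
    time_min = rep(c(-2, 0, 2), each = 2),
    channel = rep(c("green", "red"), 3),
    roi = c(410, 500, 405, 500, 330, 460),
    cytosol = c(10, 100, 5, 100, 10, 100),
    background = 0,
    prefusion_flag = rep(c(TRUE, FALSE, FALSE), each = 2)
  )
  rfi <- normalize_to_prefusion(trace)
  expect_equal(rfi$rfi_red[1], 1)
  expect_equal(rfi$rfi_green[1], 1)
  expect_equal(rfi$rfi_red, c(1, 1, 0.9))
  expect_equal(rfi$rfi_green, c(1, 1, 0.8))
  fd <- conversion(rfi$rfi_red, rfi$rfi_green)
  expect_equal(fd, c(0, 0, 100 * (0.9 - 0.8) / 0.9))
})

test_that("a constant trace normalizes to RFI identically 1 and FD 0", {
  trace <- data.frame(
    cell_id = "c1", time_min = rep(seq(-4, 10, 2), each = 2),
    channel = rep(c("green", "red"), 8),
    roi = rep(c(400, 450), 8), cytosol = 50, background = 0,
    prefusion_flag = rep(seq(-4, 10, 2) < 0, each = 2)
  )
  cv <- compute_conversion(trace, phase_boundaries = NULL)
  expect_equal(cv$rfi_red, rep(1, nrow(cv)))
  expect_equal(cv$fd_percent, rep(0, nrow(cv)))
})

test_that("background offsets cancel: FD identical with and without background", {
  cfg0 <- quiet_config()
  cfg_bg <- reporter_kinetics_config(noise_sd = 0, background_level = 50,
                                     bleach_per_exposure_red = 0,
                                     bleach_per_exposure_green = 0)
  sched <- interaction_schedule(windows = list(c(10, 40, "PCDII")))
  for (cfg in list(cfg0, cfg_bg)) {
    truth <- simulate_reporter_kinetics(cfg, sched)
    cv <- compute_conversion(sample_intensity_trace(truth))
    if (identical(cfg, cfg0)) fd0 <- cv$fd_percent else fd_bg <- cv$fd_percent
  }
  expect_equal(fd_bg, fd0, tolerance = 1e-12)
})

test_that("noiseless FD equals the ground-truth cleaved fraction as GFP decay becomes fast", {
  sched <- interaction_schedule(windows = list(c(4, 60, "PCDII")))
  cfg <- quiet_config(synthesis_rate = 0, gfp_degradation_rate = 100)
  truth <- simulate_reporter_kinetics(cfg, sched)
  cv <- compute_conversion(sample_intensity_trace(truth))
  post <- cv$time_min > 0
  sp <- spliffr:::truth_species_at(truth, cv$time_min[post])
  cleaved_fraction <- 100 * sp[, "R_c"] / (sp[, "U"] + sp[, "R_c"])
  expect_lt(max(abs(cv$fd_percent[post] - cleaved_fraction)), 1)
})

test_that("phase annotation uses half-open intervals assigned to the later phase", {
  tr <- data.frame(time_min = c(0, 10, 20, 50, 100, 110))
  pb <- list(PCDI = c(0, 20), PCDII = c(20, 100), PCDIII = c(100, 115))
  out <- annotate_phases(tr, pb)
  expect_equal(out$phase, c("PCDI", "PCDI", "PCDII", "PCDII", "PCDIII", "PCDIII"))
  # empty phase window: no timepoints, no error
  out2 <- annotate_phases(tr, list(PCDI = c(0, 20), PCDII = c(20, 100),
                                   PCDIII = c(100, 100)))
  expect_false(any(out2$phase == "PCDIII", na.rm = TRUE))
  expect_error(annotate_phases(tr, list(PCDI = c(0, 30), PCDII = c(20, 100))),
               "overlap")
})

test_that("caveat and negative flags are set from FD", {
  trace <- data.frame(
    cell_id = "c1", time_min = rep(c(-2, 0, 2, 4), each = 2),
    channel = rep(c("green", "red"), 4),
    roi = c(450, 450, 450, 450, 500, 440, 80, 450),
    cytosol = 50, background = 0,
    prefusion_flag = rep(c(TRUE, FALSE, FALSE, FALSE), each = 2)
  )
  cv <- compute_conversion(trace, phase_boundaries = NULL)
  expect_false(cv$flag_negative[2]) # FD = 0
  expect_true(cv$flag_negative[3])  # green above red
  expect_true(cv$flag_caveat[4])    # FD >= 80
})
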