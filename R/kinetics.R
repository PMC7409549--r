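# Reporter kinetics: the forward model behind the synthetic SPLIFF data.
#
# The reporter is a tripartite mCherry-Cub-GFP (CCG) fusion. While the bait
# interacts with an Nub-tagged prey, reconstituted ubiquitin is cleaved and
# the GFP moiety is released and degraded; the mCherry-bearing product (CC)
# persists. Three species are tracked:
#   U   intact reporter (red + green)
#   R_c cleaved red-bearing product
#   G_c cleaved free GFP (decays fast)
# with linear mass-action kinetics
#   dU/dt   = s - (k_cl(t) + d_r) U
#   dR_c/dt = k_cl(t) U - d_r R_c
#   dG_c/dt = k_cl(t) U - d_g G_c
# where k_cl(t) switches between an "on" rate inside interaction windows and a
# basal "off" rate outside them. Red signal is proportional to U + R_c, green
# to U + G_c.

#' Kinetic parameters of the cleavage reporter
#'
#' Bundles the rate constants and measurement parameters used by
#' [simulate_reporter_kinetics()] and [sample_intensity_trace()]. Defaults
#' describe a moderately noisy two-channel time-lapse of a polarized yeast
#' reporter; see the package vignette for the rationale behind each value.
#'
#' @param synthesis_rate reporter synthesis, molecules (intensity units) per
#'   minute after cell fusion. Before fusion the pool is assumed at steady
#'   state (`initial_reporter`). Default 0: synthesis of new reporter during
#'   the ~2 h measurement is off, so conversion can only accumulate.
#' @param cleavage_rate_on per-minute cleavage rate constant while the
#'   interaction is active.
#' @param cleavage_rate_off basal per-minute cleavage rate outside interaction
#'   windows (default 0).
#' @param gfp_degradation_rate per-minute decay of the cleaved GFP moiety.
#' @param reporter_degradation_rate per-minute turnover of the intact reporter
#'   and of the cleaved red-bearing product.
#' @param initial_reporter pre-fusion steady-state reporter amount, in
#'   intensity units.
#' @param bleach_per_exposure_red,bleach_per_exposure_green fractional signal
#'   loss per acquisition in each channel, in `[0, 1)`.
#' @param background_level extracellular background, intensity units.
#' @param noise_sd additive Gaussian noise on every measured ROI value,
#'   intensity units.
#' @param roi_fraction fraction of the cell's total signal inside the polarity
#'   ROI, in `(0, 1]`.
#' @return an object of class `reporter_kinetics_config`.
#' @export
reporter_kinetics_config <- function(synthesis_rate = 0,
                                     cleavage_rate_on = 0.05,
                                     cleavage_rate_off = 0,
                                     gfp_degradation_rate = 1.0,
                                     reporter_degradation_rate = 0.003,
                                     initial_reporter = 1000,
                                     bleach_per_exposure_red = 0.002,
                                     bleach_per_exposure_green = 0.002,
                                     background_level = 50,
                                     noise_sd = 8,
                                     roi_fraction = 0.85) {
  check_number(synthesis_rate, "synthesis_rate", lower = 0)
  check_number(cleavage_rate_on, "cleavage_rate_on", lower = 0)
  check_number(cleavage_rate_off, "cleavage_rate_off", lower = 0)
  check_number(gfp_degradation_rate, "gfp_degradation_rate", lower = 0)
  check_number(reporter_degradation_rate, "reporter_degradation_rate", lower = 0)
  check_number(initial_reporter, "initial_reporter", lower = 0)
  check_number(bleach_per_exposure_red, "bleach_per_exposure_red",
               lower = 0, upper = 1, upper_open = TRUE)
  check_number(bleach_per_exposure_green, "bleach_per_exposure_green",
               lower = 0, upper = 1, upper_open = TRUE)
  check_number(background_level, "background_level", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(roi_fraction, "roi_fraction", lower = 0, lower_open = TRUE, upper = 1)
  structure(list(
    synthesis_rate = synthesis_rate,
    cleavage_rate_on = cleavage_rate_on,
    cleavage_rate_off = cleavage_rate_off,
    gfp_degradation_rate = gfp_degradation_rate,
    reporter_degradation_rate = reporter_degradation_rate,
    initial_reporter = initial_reporter,
    bleach_per_exposure_red = bleach_per_exposure_red,
    bleach_per_exposure_green = bleach_per_exposure_green,
    background_level = background_level,
    noise_sd = noise_sd,
    roi_fraction = roi_fraction
  ), class = "reporter_kinetics_config")
}

#' Interaction schedule for a simulated cell
#'
#' Defines when, in minutes after cell fusion, the bait-prey interaction is
#' active (cleavage proceeds at the "on" rate) and how the cell is sampled.
#' Phases follow the three-stage measurement scheme: PCDI at the site of cell
#' fusion, PCDII during bud-site assembly and bud growth, PCDIII at the bud
#' neck until abscission.
#'
#' @param windows a list of `c(start_min, end_min)` pairs, or a data.frame with
#'   columns `start`, `end`, `phase`. Windows must be non-overlapping, sorted,
#'   and inside `[0, total_duration]`. Intervals are half-open `[start, end)`.
#' @param total_duration length of the post-fusion recording, minutes.
#' @param sampling_interval frame spacing in minutes; one of 2, 3, or 5.
#' @param fusion_time absolute time of cell fusion, minutes; pre-fusion frames
#'   before it are included in sampled traces. Defines t = 0 of the relative
#'   time axis.
#' @param phase_boundaries named list mapping `PCDI`, `PCDII`, `PCDIII` to
#'   `c(start, end)` in minutes after fusion (half-open intervals).
#' @return an object of class `interaction_schedule` with a `windows`
#'   data.frame (`start`, `end`, `phase`).
#' @export
interaction_schedule <- function(windows = list(),
                                 total_duration = 115,
                                 sampling_interval = 2,
                                 fusion_time = 4,
                                 phase_boundaries = list(PCDI = c(0, 20),
                                                         PCDII = c(20, 100),
                                                         PCDIII = c(100, 115))) {
  check_number(total_duration, "total_duration", lower = 0, lower_open = TRUE)
  if (!sampling_interval %in% c(2, 3, 5))
    stop_invalid("'sampling_interval' must be 2, 3 or 5 minutes")
  check_number(fusion_time, "fusion_time", lower = 0)
  if (is.data.frame(windows)) {
    win <- windows
    if (is.null(win$phase)) win$phase <- NA_character_
  } else {
    win <- data.frame(
      start = vapply(windows, function(w) as.numeric(w[[1]]), 0),
      end = vapply(windows, function(w) as.numeric(w[[2]]), 0),
      phase = vapply(windows, function(w)
        if (length(w) >= 3) as.character(w[[3]]) else NA_character_, ""),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(win)) {
    if (any(win$end <= win$start))
      stop_invalid("interaction windows must have end > start")
    if (any(win$start < 0) || any(win$end > total_duration))
      stop_invalid("interaction windows must lie within [0, total_duration]")
    win <- win[order(win$start), , drop = FALSE]
    if (nrow(win) > 1 && any(win$start[-1] < win$end[-nrow(win)]))
      stop_invalid("interaction windows must not overlap")
    bad <- !is.na(win$phase) & !win$phase %in% c("PCDI", "PCDII", "PCDIII")
    if (any(bad)) stop_invalid("window phase labels must be PCDI, PCDII or PCDIII")
  }
  pb <- validate_phase_boundaries(phase_boundaries, total_duration)
  structure(list(
    windows = win,
    total_duration = total_duration,
    sampling_interval = sampling_interval,
    fusion_time = fusion_time,
    phase_boundaries = pb
  ), class = "interaction_schedule")
}

validate_phase_boundaries <- function(pb, total_duration) {
  if (is.null(pb) || !length(pb)) return(list())
  phases <- names(pb)
  if (!all(phases %in% c("PCDI", "PCDII", "PCDIII")))
    stop_invalid("phase boundaries must be named PCDI, PCDII, PCDIII")
  m <- do.call(rbind, pb)
  if (any(m[, 2] < m[, 1]))
    stop_invalid("phase boundaries must have end >= start")
  ord <- order(m[, 1])
  if (nrow(m) > 1 && any(m[ord, 1][-1] < m[ord, 2][-nrow(m)]))
    stop_invalid("phase boundaries must not overlap")
  want <- intersect(c("PCDI", "PCDII", "PCDIII"), phases)
  if (!identical(phases[ord], want))
    stop_invalid("phases must be ordered PCDI < PCDII < PCDIII")
  pb
}

# cleavage rate at post-fusion time t (vectorized)
cleavage_rate_at <- function(t, config, schedule) {
  k <- rep(config$cleavage_rate_off, length(t))
  win <- schedule$windows
  if (nrow(win)) {
    for (i in seq_len(nrow(win))) {
      k[t >= win$start[i] & t < win$end[i]] <- config$cleavage_rate_on
    }
  }
  k[t < 0] <- 0 # no reconstitution before fusion
  k
}

# Classical RK4 for the three-species system. The system is linear with
# constant coefficients within each schedule segment, x' = A x + b, so one
# RK4 step is exactly the affine map
#   x -> M x + c,  M = I + hA + (hA)^2/2 + (hA)^3/6 + (hA)^4/24,
#                  c = (hI + h^2 A/2 + h^3 A^2/6 + h^4 A^3/24) b.
# Precomputing (M, c) once per segment makes the fixed-step integration fast
# without changing the method or its error behaviour.
rk4_affine_map <- function(h, s, k, d_r, d_g) {
  A <- matrix(c(-(k + d_r), k, k,
                0, -d_r, 0,
                0, 0, -d_g), 3, 3)
  b <- c(s, 0, 0)
  I3 <- diag(3)
  hA <- h * A
  hA2 <- hA %*% hA
  hA3 <- hA2 %*% hA
  hA4 <- hA3 %*% hA
  M <- I3 + hA + hA2 / 2 + hA3 / 6 + hA4 / 24
  Cc <- (h * I3 + h * hA / 2 + h * hA2 / 6 + h * hA3 / 24) %*% b
  list(M = M, c = as.numeric(Cc))
}

#' Simulate noiseless reporter-species trajectories
#'
#' Integrates the three-species cleavage/degradation system over the
#' post-fusion recording with a fixed-step fourth-order Runge-Kutta scheme
#' (step <= `step_min` minutes, segment boundaries hit exactly). Before fusion
#' the reporter pool is held at its steady-state value and no cleavage occurs.
#'
#' @param config a [reporter_kinetics_config()].
#' @param schedule an [interaction_schedule()].
#' @param seed integer seed stored with the ground truth (the trajectories
#'   themselves are deterministic; the seed feeds downstream sampling).
#' @param step_min maximum integrator step in minutes.
#' @param times optional extra post-fusion times (minutes) to include as
#'   output nodes, e.g. the sampling grid.
#' @return an object of class `spliff_ground_truth`: a list with `trajectory`
#'   (data.frame `time`, `U`, `R_c`, `G_c` on the integration grid, time in
#'   minutes after fusion), `config`, `schedule`, `seed`.
#' @export
simulate_reporter_kinetics <- function(config, schedule, seed = 1L,
                                       step_min = 0.05, times = NULL) {
  stopifnot(inherits(config, "reporter_kinetics_config"),
            inherits(schedule, "interaction_schedule"))
  check_number(step_min, "step_min", lower = 0, lower_open = TRUE)
  tmax <- schedule$total_duration
  # the sampling grid is always included as output nodes
  fr <- frame_times(schedule)
  times <- unique(c(times, fr$time[!fr$prefusion]))
  breaks <- sort(unique(c(0, tmax,
                          schedule$windows$start, schedule$windows$end,
                          times[times >= 0 & times <= tmax])))
  s <- config$synthesis_rate
  d_r <- config$reporter_degradation_rate
  d_g <- config$gfp_degradation_rate
  # stiffness guard: keep |lambda| h small for the fastest decay mode so the
  # explicit RK4 step stays stable and accurate even for rapid GFP turnover
  lambda_max <- max(config$cleavage_rate_on + d_r,
                    config$cleavage_rate_off + d_r, d_r, d_g, 1e-12)
  step_min <- min(step_min, 0.2 / lambda_max)
  # integrate segment by segment (constant cleavage rate within each); every
  # segment uses a uniform step <= step_min, so boundaries are hit exactly
  nodes <- 0
  traj_list <- list(matrix(c(config$initial_reporter, 0, 0), 1, 3))
  state <- traj_list[[1]][1, ]
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; b <- breaks[i + 1]
    nseg <- max(1L, ceiling((b - a) / step_min))
    h <- (b - a) / nseg
    k <- cleavage_rate_at((a + b) / 2, config, schedule)
    map <- rk4_affine_map(h, s, k, d_r, d_g)
    seg <- matrix(0, nseg, 3)
    for (j in seq_len(nseg)) {
      state <- map$M %*% state + map$c
      seg[j, ] <- state
    }
    traj_list[[i + 1]] <- seg
    nodes <- c(nodes, a + h * seq_len(nseg))
  }
  traj <- do.call(rbind, traj_list)
  colnames(traj) <- c("U", "R_c", "G_c")
  traj[traj < 0 & traj > -1e-9] <- 0 # clip round-off undershoot only
  structure(list(
    trajectory = data.frame(time = nodes, U = traj[, 1], R_c = traj[, 2],
                            G_c = traj[, 3]),
    config = config,
    schedule = schedule,
    seed = as.integer(seed)
  ), class = "spliff_ground_truth")
}

# Evaluate ground-truth species at arbitrary post-fusion times. Negative
# times return the pre-fusion steady state. Requested times must be
# integration nodes (the simulator includes the sampling grid as nodes).
truth_species_at <- function(truth, t) {
  tr <- truth$trajectory
  out <- matrix(NA_real_, length(t), 3,
                dimnames = list(NULL, c("U", "R_c", "G_c")))
  pre <- t < 0
  out[pre, ] <- rep(c(truth$config$initial_reporter, 0, 0), each = sum(pre))
  idx <- match(round(t[!pre], 9), round(tr$time, 9))
  if (anyNA(idx))
    stop_invalid("requested times are not integration nodes; pass them via 'times='")
  out[!pre, ] <- as.matrix(tr[idx, c("U", "R_c", "G_c")])
  out
}

#' True conversion curve implied by a ground truth
#'
#' Computes the noiseless FD(t) that ideal quantification would recover:
#' red signal is proportional to `U + R_c`, green to `U + G_c`, each
#' normalized to its pre-fusion value, and
#' `FD = 100 (RFI_red - RFI_green) / RFI_red`.
#'
#' @param truth a `spliff_ground_truth`.
#' @param t post-fusion times (minutes); defaults to the integration grid.
#' @return data.frame with `time` and `fd_percent`.
#' @export
true_conversion <- function(truth, t = NULL) {
  if (is.null(t)) t <- truth$trajectory$time
  sp <- truth_species_at(truth, t)
  u0 <- truth$config$initial_reporter
  rfi_red <- (sp[, "U"] + sp[, "R_c"]) / u0
  rfi_green <- (sp[, "U"] + sp[, "G_c"]) / u0
  data.frame(time = t, fd_percent = 100 * (rfi_red - rfi_green) / rfi_red)
}

#' @export
print.spliff_ground_truth <- function(x, ...) {
  cat("Reporter-kinetics ground truth\n")
  cat(sprintf("  duration: %g min post-fusion, %d integration nodes\n",
              x$schedule$total_duration, nrow(x$trajectory)))
  w <- x$schedule$windows
  if (nrow(w)) {
    cat(sprintf("  interaction windows: %s\n",
                paste(sprintf("[%g, %g) %s", w$start, w$end, w$phase),
                      collapse = ", ")))
  } else cat("  interaction windows: none\n")
  fd <- true_conversion(x)
  cat(sprintf("  final noiseless conversion: %.1f%%\n",
              fd$fd_percent[nrow(fd)]))
  invisible(x)
}
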