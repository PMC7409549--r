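# Turning noiseless kinetics into measured two-channel ROI traces.

# Frame schedule implied by an interaction_schedule: frames at a fixed
# interval in absolute time starting at 0; cell fusion happens at
# schedule$fusion_time, so frames before it are pre-fusion. Returned times are
# in minutes relative to fusion (the kinetic clock).
frame_times <- function(schedule) {
  abs_t <- seq(0, schedule$fusion_time + schedule$total_duration,
               by = schedule$sampling_interval)
  rel <- abs_t - schedule$fusion_time
  data.frame(frame = seq_along(abs_t), time = rel, prefusion = rel < 0)
}

#' Sample a measured two-channel intensity trace from a ground truth
#'
#' Emits, for every frame and both channels, the three ROI readings that the
#' quantification step consumes: the polarity-site ROI, a cytosolic ROI, and
#' an extracellular background ROI. The site ROI carries `roi_fraction` of the
#' channel's total signal, the cytosol the remainder; each channel is dimmed
#' by its cumulative per-exposure bleach factor; background is added to the
#' intracellular readings and independent Gaussian noise to all three.
#'
#' @param truth a `spliff_ground_truth` from [simulate_reporter_kinetics()].
#' @param seed integer seed for the measurement noise.
#' @param cell_id identifier stored in the output.
#' @return a data.frame of class `intensity_trace` with columns `cell_id`,
#'   `time_min` (minutes after fusion; pre-fusion frames are negative),
#'   `channel` (`"red"`/`"green"`), `roi`, `cytosol`, `background`,
#'   `prefusion_flag`. Phase boundaries from the schedule are attached as the
#'   `phase_boundaries` attribute.
#' @export
sample_intensity_trace <- function(truth, seed = truth$seed, cell_id = "cell1") {
  stopifnot(inherits(truth, "spliff_ground_truth"))
  config <- truth$config
  schedule <- truth$schedule
  fr <- frame_times(schedule)
  sp <- truth_species_at(truth, fr$time)
  total <- cbind(red = sp[, "U"] + sp[, "R_c"],
                 green = sp[, "U"] + sp[, "G_c"])
  bleach <- c(red = config$bleach_per_exposure_red,
              green = config$bleach_per_exposure_green)
  set.seed(as.integer(seed))
  rows <- vector("list", 2L)
  for (ch in c("red", "green")) {
    bfac <- (1 - bleach[[ch]])^(fr$frame - 1)
    sig <- total[, ch] * bfac
    n <- nrow(fr)
    noise <- matrix(stats::rnorm(3 * n, 0, config$noise_sd), n, 3)
    rows[[ch]] <- data.frame(
      cell_id = cell_id,
      time_min = fr$time,
      channel = ch,
      roi = config$roi_fraction * sig + config$background_level + noise[, 1],
      cytosol = (1 - config$roi_fraction) * sig + config$background_level + noise[, 2],
      background = config$background_level + noise[, 3],
      prefusion_flag = fr$prefusion,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(rows[["red"]], rows[["green"]])
  out <- out[order(out$time_min, out$channel), ]
  rownames(out) <- NULL
  structure(out,
            phase_boundaries = schedule$phase_boundaries,
            class = c("intensity_trace", "data.frame"))
}

#' Simulate a population of cells with jittered fusion times
#'
#' Repeats the single-cell simulation `n_cells` times. Each cell's fusion time
#' is jittered by a Gaussian offset (truncated at 0) so that the frame grid
#' falls differently relative to the kinetic clock, as in real matings, and
#' measurement noise is independent between cells. Ground truth is retained
#' per cell for validation.
#'
#' @param config a [reporter_kinetics_config()].
#' @param schedule_template an [interaction_schedule()]; per-cell schedules
#'   differ only in `fusion_time`.
#' @param n_cells number of cells (>= 1).
#' @param fusion_jitter_sd SD of the fusion-time jitter, minutes.
#' @param seed integer master seed; all per-cell seeds derive from it.
#' @return list with `traces` (list of `intensity_trace`) and `truths`
#'   (list of `spliff_ground_truth`), class `spliff_population`.
#' @export
simulate_population <- function(config, schedule_template, n_cells = 20,
                                fusion_jitter_sd = 1, seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  check_number(fusion_jitter_sd, "fusion_jitter_sd", lower = 0)
  seeds <- derive_seeds(seed, 2L * n_cells)
  set.seed(seeds[1L])
  jitter <- if (fusion_jitter_sd > 0) stats::rnorm(n_cells, 0, fusion_jitter_sd) else rep(0, n_cells)
  traces <- vector("list", n_cells)
  truths <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    sched <- schedule_template
    sched$fusion_time <- max(0, schedule_template$fusion_time + jitter[i])
    truth <- simulate_reporter_kinetics(config, sched, seed = seeds[n_cells + i])
    id <- sprintf("cell%03d", i)
    traces[[i]] <- sample_intensity_trace(truth, seed = seeds[n_cells + i],
                                          cell_id = id)
    truths[[i]] <- truth
  }
  names(traces) <- names(truths) <- vapply(traces, function(x) x$cell_id[1], "")
  structure(list(traces = traces, truths = truths, seed = as.integer(seed)),
            class = "spliff_population")
}

#' @export
print.spliff_population <- function(x, ...) {
  cat(sprintf("Simulated SPLIFF population: %d cells, seed %d\n",
              length(x$traces), x$seed))
  invisible(x)
}
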