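# Optional synthetic-frame rendering: draws the three-ROI geometry into small
# z-stacks so that SUM projection + mean-gray-value quantification can be
# exercised end to end against the tabular trace.

#' Frame geometry for synthetic image rendering
#'
#' @param width,height frame size in pixels (each <= 256).
#' @param n_z number of z slices (<= 5).
#' @param roi_center,roi_radius polarity-site disc (pixels).
#' @param cytosol_center,cytosol_radius cytosolic disc.
#' @param background_center,background_radius extracellular disc.
#' @return list of class `frame_geometry`.
#' @export
frame_geometry <- function(width = 64, height = 64, n_z = 5,
                           roi_center = c(16, 32), roi_radius = 5,
                           cytosol_center = c(32, 32), cytosol_radius = 6,
                           background_center = c(54, 10), background_radius = 5) {
  if (width > 256 || height > 256 || n_z > 5)
    stop_invalid("frame geometry exceeds the supported size (256 x 256 x 5)")
  structure(list(width = width, height = height, n_z = n_z,
                 roi_center = roi_center, roi_radius = roi_radius,
                 cytosol_center = cytosol_center,
                 cytosol_radius = cytosol_radius,
                 background_center = background_center,
                 background_radius = background_radius),
            class = "frame_geometry")
}

disc_mask <- function(width, height, center, radius) {
  x <- matrix(rep(seq_len(width), each = height), height, width)
  y <- matrix(rep(seq_len(height), width), height, width)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

#' Render a ground truth into synthetic two-channel z-stacks
#'
#' For every frame of the sampling schedule, distributes the channel's ROI and
#' cytosol signal (after the cumulative bleach factor) uniformly over the
#' corresponding discs across the z slices, on top of a uniform background, so
#' that a SUM projection followed by mean-gray-value measurement inside each
#' disc reproduces the tabular readings of [sample_intensity_trace()].
#'
#' @param truth a `spliff_ground_truth`.
#' @param geometry a [frame_geometry()].
#' @return list of class `synthetic_frames`: per frame, a list with `time`,
#'   `prefusion` and one `height x width x n_z` array per channel.
#' @export
render_synthetic_frames <- function(truth, geometry = frame_geometry()) {
  stopifnot(inherits(truth, "spliff_ground_truth"),
            inherits(geometry, "frame_geometry"))
  config <- truth$config
  schedule <- truth$schedule
  fr <- frame_times(schedule)
  sp <- truth_species_at(truth, fr$time)
  total <- cbind(red = sp[, "U"] + sp[, "R_c"],
                 green = sp[, "U"] + sp[, "G_c"])
  bleach <- c(red = config$bleach_per_exposure_red,
              green = config$bleach_per_exposure_green)
  masks <- list(
    roi = disc_mask(geometry$width, geometry$height, geometry$roi_center,
                    geometry$roi_radius),
    cytosol = disc_mask(geometry$width, geometry$height,
                        geometry$cytosol_center, geometry$cytosol_radius)
  )
  frames <- vector("list", nrow(fr))
  for (i in seq_len(nrow(fr))) {
    stack <- list()
    for (ch in c("red", "green")) {
      bfac <- (1 - bleach[[ch]])^(fr$frame[i] - 1)
      sig <- total[i, ch] * bfac
      slice <- matrix(config$background_level / geometry$n_z,
                      geometry$height, geometry$width)
      slice[masks$roi] <- slice[masks$roi] +
        config$roi_fraction * sig / geometry$n_z
      slice[masks$cytosol] <- slice[masks$cytosol] +
        (1 - config$roi_fraction) * sig / geometry$n_z
      stack[[ch]] <- array(rep(slice, geometry$n_z),
                           dim = c(geometry$height, geometry$width,
                                   geometry$n_z))
    }
    frames[[i]] <- list(time = fr$time[i], prefusion = fr$prefusion[i],
                        red = stack$red, green = stack$green)
  }
  structure(frames, geometry = geometry, class = "synthetic_frames")
}

#' Quantify synthetic frames back into a tabular intensity trace
#'
#' SUM-projects each z-stack and measures the mean gray value inside the
#' three ROI discs of the geometry, emitting the same long-format table as
#' [sample_intensity_trace()].
#'
#' @param frames a `synthetic_frames` object.
#' @param cell_id identifier for the output.
#' @return data.frame of class `intensity_trace`.
#' @export
quantify_frames <- function(frames, cell_id = "cell1") {
  geometry <- attr(frames, "geometry")
  masks <- list(
    roi = disc_mask(geometry$width, geometry$height, geometry$roi_center,
                    geometry$roi_radius),
    cytosol = disc_mask(geometry$width, geometry$height,
                        geometry$cytosol_center, geometry$cytosol_radius),
    background = disc_mask(geometry$width, geometry$height,
                           geometry$background_center,
                           geometry$background_radius)
  )
  rows <- lapply(frames, function(f) {
    do.call(rbind, lapply(c("red", "green"), function(ch) {
      proj <- apply(f[[ch]], c(1, 2), sum) # SUM projection over z
      data.frame(cell_id = cell_id, time_min = f$time, channel = ch,
                 roi = mean(proj[masks$roi]),
                 cytosol = mean(proj[masks$cytosol]),
                 background = mean(proj[masks$background]),
                 prefusion_flag = f$prefusion, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$time_min, out$channel), ]
  rownames(out) <- NULL
  structure(out, class = c("intensity_trace", "data.frame"))
}
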