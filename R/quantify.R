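# Quantification: raw ROI readings -> relative intensities -> RFI -> FD(t).
#
# Two background conventions coexist in routine practice and both are exposed:
#  * relative_intensity() — the comparative-localization ratio
#      I_rel = (I_fluorescence - I_background) / (I_cytosol - I_background)
#  * localized_intensity() — the SPLIFF path: the intracellular (cytosolic)
#      background is subtracted from the localized signal, FI = I_roi - I_cyt.
# The conversion statistic is FD(t) = 100 (RFI_red - RFI_green) / RFI_red,
# where RFI is FI normalized to the last pre-fusion frame.

#' Relative fluorescence intensity of one measurement
#'
#' Ratio of background-subtracted site signal to background-subtracted
#' cytosolic signal, used to compare a protein's enrichment between strains.
#' Invariant under a common additive offset on all three readings.
#'
#' @param roi,cytosol,background mean gray values of the site, cytosol and
#'   extracellular ROIs (vectorized).
#' @param denominator_floor smallest admissible `|cytosol - background|`;
#'   below it the timepoint is flagged invalid (`NA`) rather than producing
#'   an unstable ratio.
#' @return numeric vector; `NA` where the denominator is degenerate.
#' @export
relative_intensity <- function(roi, cytosol, background, denominator_floor = 1e-8) {
  den <- cytosol - background
  out <- (roi - background) / den
  out[abs(den) < denominator_floor] <- NA_real_
  out
}

#' Localized fluorescence intensity (cytosol-subtracted)
#'
#' The SPLIFF quantification: subtract the intracellular (cytosolic)
#' background from the localized signal. Negative values are retained; they
#' occur at low signal and are handled downstream.
#'
#' @param roi,cytosol mean gray values (vectorized); missing cytosol gives NA.
#' @return numeric vector `roi - cytosol`.
#' @export
localized_intensity <- function(roi, cytosol) {
  roi - cytosol
}

#' Conversion statistic FD from per-channel relative intensities
#'
#' `FD = 100 (rfi_red - rfi_green) / rfi_red`, the percentage of reporter
#' converted from the intact (red+green) to the cleaved (red-only) species.
#' Values outside `[0, 100]` are retained (noise); non-positive `rfi_red`
#' yields `NA` (invalid timepoint).
#'
#' @param rfi_red,rfi_green unitless relative fluorescence intensities.
#' @return FD in percent.
#' @export
conversion <- function(rfi_red, rfi_green) {
  out <- 100 * (rfi_red - rfi_green) / rfi_red
  out[!is.finite(rfi_red) | rfi_red <= 0] <- NA_real_
  out
}

#' Normalize a cell's localized intensities to the pre-fusion reference
#'
#' Computes per-channel localized intensities FI = roi - cytosol on the
#' shared time grid, then divides each channel by its value at the reference
#' timepoint: by default the single last pre-fusion frame, optionally the
#' mean of the last `reference_frames` pre-fusion frames.
#'
#' @param trace an `intensity_trace` (long data.frame, both channels).
#' @param reference_frames number of trailing pre-fusion frames averaged for
#'   the reference (default 1: the last pre-fusion frame only).
#' @return data.frame `time_min`, `rfi_red`, `rfi_green` on the post-fusion
#'   grid (reference frame included with RFI exactly 1 when
#'   `reference_frames = 1`); or `NULL` (with a warning) if the cell has no
#'   usable reference.
#' @export
normalize_to_prefusion <- function(trace, reference_frames = 1L) {
  reference_frames <- check_count(reference_frames, "reference_frames")
  wide <- trace_to_wide(trace)
  pre <- which(wide$prefusion_flag)
  if (!length(pre)) {
    warning(sprintf("cell %s excluded: no pre-fusion frames", wide$cell_id[1]))
    return(NULL)
  }
  ref_idx <- utils::tail(pre, reference_frames)
  ref_red <- mean(wide$fi_red[ref_idx])
  ref_green <- mean(wide$fi_green[ref_idx])
  if (!is.finite(ref_red) || !is.finite(ref_green) ||
      ref_red == 0 || ref_green == 0) {
    warning(sprintf("cell %s excluded: zero pre-fusion reference", wide$cell_id[1]))
    return(NULL)
  }
  data.frame(time_min = wide$time_min,
             rfi_red = wide$fi_red / ref_red,
             rfi_green = wide$fi_green / ref_green,
             prefusion_flag = wide$prefusion_flag)
}

# long (channel rows) -> wide (fi_red / fi_green columns), checking grid
trace_to_wide <- function(trace) {
  stopifnot(all(c("cell_id", "time_min", "channel", "roi", "cytosol") %in%
                  names(trace)))
  red <- trace[trace$channel == "red", ]
  green <- trace[trace$channel == "green", ]
  red <- red[order(red$time_min), ]
  green <- green[order(green$time_min), ]
  if (!isTRUE(all.equal(red$time_min, green$time_min)))
    stop_invalid("cell %s: red and green channels are not on a shared time grid",
                 trace$cell_id[1])
  if (any(diff(red$time_min) <= 0))
    stop_invalid("cell %s: time grid is not strictly increasing", trace$cell_id[1])
  pref <- if ("prefusion_flag" %in% names(red)) red$prefusion_flag else red$time_min < 0
  data.frame(cell_id = red$cell_id,
             time_min = red$time_min,
             fi_red = localized_intensity(red$roi, red$cytosol),
             fi_green = localized_intensity(green$roi, green$cytosol),
             prefusion_flag = pref)
}

#' Compute a per-cell conversion trace
#'
#' Full quantification of one cell: localized intensities, pre-fusion
#' normalization, FD(t), flags, and phase annotation. Pre-fusion frames other
#' than the reference are dropped; the reference frame (t of the last
#' pre-fusion frame) is retained with FD = 0 by construction.
#'
#' @param trace an `intensity_trace`.
#' @param phase_boundaries named list `PCDI`/`PCDII`/`PCDIII` ->
#'   `c(start, end)` minutes after fusion; defaults to the trace's
#'   `phase_boundaries` attribute.
#' @param reference_frames see [normalize_to_prefusion()].
#' @param caveat_threshold conversion level (percent) at and above which the
#'   interpretability caveat flag is set (default 80: high conversions are
#'   difficult to interpret).
#' @return data.frame of class `conversion_trace`: `cell_id`, `time_min`,
#'   `rfi_red`, `rfi_green`, `fd_percent`, `phase`, `flag_negative`,
#'   `flag_caveat`; or `NULL` if the cell was excluded.
#' @export
compute_conversion <- function(trace, phase_boundaries = NULL,
                               reference_frames = 1L, caveat_threshold = 80) {
  if (is.null(phase_boundaries))
    phase_boundaries <- attr(trace, "phase_boundaries")
  rfi <- normalize_to_prefusion(trace, reference_frames)
  if (is.null(rfi)) return(NULL)
  keep <- !rfi$prefusion_flag
  # retain the reference frame itself (FD = 0 anchor)
  ref_i <- max(which(rfi$prefusion_flag))
  keep[ref_i] <- TRUE
  rfi <- rfi[keep, , drop = FALSE]
  fd <- conversion(rfi$rfi_red, rfi$rfi_green)
  out <- data.frame(cell_id = trace$cell_id[1],
                    time_min = rfi$time_min,
                    rfi_red = rfi$rfi_red,
                    rfi_green = rfi$rfi_green,
                    fd_percent = fd,
                    phase = NA_character_,
                    flag_negative = !is.na(fd) & fd < 0,
                    flag_caveat = !is.na(fd) & fd >= caveat_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- structure(out, class = c("conversion_trace", "data.frame"))
  if (!is.null(phase_boundaries) && length(phase_boundaries))
    out <- annotate_phases(out, phase_boundaries)
  out
}

#' Annotate a conversion trace with measurement phases
#'
#' Assigns each timepoint to PCDI, PCDII or PCDIII using half-open intervals
#' `[start, end)`: a timepoint exactly on a boundary belongs to the later
#' phase. Timepoints outside all intervals stay unassigned (`NA`).
#'
#' @param trace a `conversion_trace` (or any data.frame with `time_min`).
#' @param phase_boundaries named list of `c(start, end)` per phase; validated
#'   for ordering and non-overlap.
#' @return the trace with its `phase` column filled.
#' @export
annotate_phases <- function(trace, phase_boundaries) {
  pb <- validate_phase_boundaries(phase_boundaries, Inf)
  phase <- rep(NA_character_, nrow(trace))
  for (ph in names(pb)) {
    b <- pb[[ph]]
    phase[trace$time_min >= b[1] & trace$time_min < b[2]] <- ph
  }
  trace$phase <- phase
  trace
}

#' @export
print.conversion_trace <- function(x, ...) {
  cat(sprintf("Conversion trace for %s: %d timepoints, FD %.1f%% -> %.1f%%\n",
              x$cell_id[1], nrow(x),
              x$fd_percent[1], x$fd_percent[nrow(x)]))
  NextMethod()
}
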