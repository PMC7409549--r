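# The user-facing model fit: traces in, population curve + slopes + calls out.

#' Fit the SPLIFF interaction model to a set of cells
#'
#' End-to-end analysis of one bait-prey pair: quantify each cell's conversion
#' trace, pool them into a loess population curve, estimate sliding-window
#' slopes with significance, and apply the calling rules (optionally vetoed
#' by a negative-control pair analysed on the same grid).
#'
#' @param traces list of `intensity_trace` data.frames (or a
#'   `spliff_population`), the bait-prey cells.
#' @param control_traces same, for the non-interacting control pair; `NULL`
#'   disables the control veto (with a warning at the calling step).
#' @param phase_boundaries named list `PCDI`/`PCDII`/`PCDIII` ->
#'   `c(start, end)` minutes; defaults to the first trace's attribute.
#' @param span loess span for the population curve.
#' @param alpha per-window significance level.
#' @param slope_floor minimum slope (percent/min) below the conversion
#'   threshold.
#' @param conversion_threshold percent conversion switching the slope rule
#'   (default 70).
#' @param caveat_threshold percent conversion flagged hard-to-interpret
#'   (default 80).
#' @param window_points grid points per sliding window (default 3).
#' @return object of class `spliff_fit` with components `conversion_traces`,
#'   `curve`, `slopes`, `calls`, `profile`, `control` (the control pair's
#'   curve and slopes, if any) and the parameters used.
#' @seealso [plot.spliff_fit()], [recover_schedule_benchmark()]
#' @export
spliff <- function(traces, control_traces = NULL, phase_boundaries = NULL,
                   span = 0.25, alpha = 0.05, slope_floor = 1,
                   conversion_threshold = 70, caveat_threshold = 80,
                   window_points = 3L) {
  if (inherits(traces, "spliff_population")) traces <- traces$traces
  if (inherits(control_traces, "spliff_population"))
    control_traces <- control_traces$traces
  if (is.null(phase_boundaries))
    phase_boundaries <- attr(traces[[1]], "phase_boundaries")
  conv <- lapply(traces, compute_conversion,
                 phase_boundaries = phase_boundaries,
                 caveat_threshold = caveat_threshold)
  conv <- conv[!vapply(conv, is.null, TRUE)]
  curve <- pool_and_fit_loess(conv, span = span)
  slopes <- sliding_window_slopes(curve, window_points = window_points)
  control <- NULL
  control_slopes <- NULL
  if (!is.null(control_traces)) {
    cconv <- lapply(control_traces, compute_conversion,
                    phase_boundaries = phase_boundaries,
                    caveat_threshold = caveat_threshold)
    cconv <- cconv[!vapply(cconv, is.null, TRUE)]
    ccurve <- pool_and_fit_loess(cconv, span = span, grid = curve$time)
    control_slopes <- sliding_window_slopes(ccurve,
                                            window_points = window_points)
    control <- list(conversion_traces = cconv, curve = ccurve,
                    slopes = control_slopes)
  }
  calls <- call_interactions(slopes, control_slopes, alpha = alpha,
                             slope_floor = slope_floor,
                             conversion_threshold = conversion_threshold,
                             caveat_threshold = caveat_threshold)
  profile <- build_profile(list(pair = calls),
                           phase_boundaries = phase_boundaries)
  structure(list(
    conversion_traces = conv,
    curve = curve,
    slopes = slopes,
    calls = calls,
    profile = profile,
    control = control,
    phase_boundaries = phase_boundaries,
    params = list(span = span, alpha = alpha, slope_floor = slope_floor,
                  conversion_threshold = conversion_threshold,
                  caveat_threshold = caveat_threshold,
                  window_points = window_points)
  ), class = "spliff_fit")
}

#' @export
print.spliff_fit <- function(x, ...) {
  cat(sprintf("SPLIFF interaction fit: %d cells, %d windows, %d called\n",
              attr(x$curve, "n_cells"), nrow(x$calls), sum(x$calls$called)))
  iv <- x$profile$intervals
  if (nrow(iv)) {
    for (i in seq_len(nrow(iv)))
      cat(sprintf("  interaction %g-%g min\n", iv$t_start[i], iv$t_end[i]))
  }
  invisible(x)
}

#' @export
summary.spliff_fit <- function(object, ...) {
  cat(sprintf("SPLIFF interaction fit (span %.2f, alpha %.3g, slope floor %g %%/min)\n",
              object$params$span, object$params$alpha, object$params$slope_floor))
  cat(sprintf("  cells: %d; pooled points: %d\n", attr(object$curve, "n_cells"),
              nrow(attr(object$curve, "points"))))
  cat(sprintf("  conversion at end of recording: %.1f%% (95%% CI %.1f-%.1f)\n",
              object$curve$fd_fit[nrow(object$curve)],
              object$curve$lower[nrow(object$curve)],
              object$curve$upper[nrow(object$curve)]))
  cat(sprintf("  windows called: %d of %d (%d with the >=80%% caveat)\n",
              sum(object$calls$called), nrow(object$calls),
              sum(object$calls$called & object$calls$flag_caveat)))
  ph <- object$profile$calls$phase
  if (any(!is.na(ph))) {
    tab <- tapply(object$profile$calls$called, ph, sum)
    cat("  called windows by phase:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
coef.spliff_fit <- function(object, ...) {
  object$calls
}

#' Predicted population conversion at new times
#'
#' @param object a `spliff_fit`.
#' @param newtimes times (minutes after fusion) inside the fitted range;
#'   defaults to the fit grid.
#' @param ... unused.
#' @return data.frame `time`, `fd_fit`.
#' @export
predict.spliff_fit <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) return(object$curve[c("time", "fd_fit")])
  data.frame(time = newtimes,
             fd_fit = stats::predict(attr(object$curve, "loess"),
                                     data.frame(time = newtimes)))
}

#' @export
fitted.spliff_fit <- function(object, ...) object$curve$fd_fit

#' @export
residuals.spliff_fit <- function(object, ...) {
  stats::residuals(attr(object$curve, "loess"))
}

#' Plot a SPLIFF fit: conversion curve and interaction windows
#'
#' Draws the pooled single-cell conversion points, the loess population curve
#' with its 95% band, and marks called windows along the top, in the style of
#' a conversion-versus-time panel.
#'
#' @param x a `spliff_fit`.
#' @param show_calls draw called windows as filled boxes at the top margin.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spliff_fit <- function(x, show_calls = TRUE, ...) {
  pts <- attr(x$curve, "points")
  graphics::plot(pts$time, pts$fd, col = "grey70", pch = 16, cex = 0.5,
                 xlab = "time after cell fusion (min)",
                 ylab = "conversion FD (%)",
                 ylim = range(c(pts$fd, x$curve$upper, 105), na.rm = TRUE), ...)
  graphics::polygon(c(x$curve$time, rev(x$curve$time)),
                    c(x$curve$lower, rev(x$curve$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  graphics::lines(x$curve$time, x$curve$fd_fit, col = "steelblue", lwd = 2)
  graphics::abline(h = c(70, 80), lty = 3, col = "grey50")
  if (show_calls && any(x$calls$called)) {
    y <- max(c(pts$fd, 100), na.rm = TRUE) + 2
    called <- x$calls[x$calls$called, ]
    graphics::rect(called$t_start, y, called$t_end, y + 3,
                   col = "royalblue", border = NA)
  }
  invisible(x)
}
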