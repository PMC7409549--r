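# Population-level inference: pooled loess curve, sliding-window slopes,
# and the threshold/veto rules that turn slopes into interaction calls.

#' Pool conversion traces and fit a local-regression population curve
#'
#' All (time, FD) points from all cells are pooled and fitted with locally
#' weighted polynomial regression (degree 2, tricube weights), giving the
#' population conversion curve and a 95% pointwise confidence band from the
#' fit's standard errors. The curve is evaluated on a common grid at the
#' finest sampling interval present.
#'
#' @param traces list of `conversion_trace` data.frames (>= 2 cells, each with
#'   >= 4 post-fusion timepoints).
#' @param span loess span (fraction of pooled points in each local window).
#' @param grid optional evaluation grid (minutes); defaults to multiples of
#'   the finest sampling interval inside the pooled time range.
#' @return object of class `population_curve`: data.frame `time`, `fd_fit`,
#'   `lower`, `upper` plus attributes `n_cells`, `span`, `points` (the pooled
#'   data actually fitted).
#' @export
pool_and_fit_loess <- function(traces, span = 0.25, grid = NULL) {
  traces <- traces[!vapply(traces, is.null, TRUE)]
  if (length(traces) < 2)
    stop_invalid("need at least 2 cells to fit a population curve")
  npost <- vapply(traces, function(tr) sum(tr$time_min >= 0), 0L)
  if (any(npost < 4))
    stop_invalid("every cell needs >= 4 post-fusion timepoints (worst has %d)",
                 min(npost))
  pooled <- do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = tr$cell_id, time = tr$time_min, fd = tr$fd_percent)))
  pooled <- pooled[is.finite(pooled$fd) & pooled$time >= 0, ]
  n <- nrow(pooled)
  q <- floor(span * n)
  if (q < 4)
    stop_invalid("span %.3g gives local windows of %d points; need >= 4 (increase span or pool more cells)",
                 span, q)
  fit <- stats::loess(fd ~ time, data = pooled, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct",
                                                     statistics = "exact"))
  if (is.null(grid)) {
    dt <- min(vapply(traces, function(tr) min(diff(sort(unique(tr$time_min)))), 0))
    grid <- seq(0, max(pooled$time), by = dt)
    grid <- grid[grid >= min(pooled$time)]
  }
  pr <- stats::predict(fit, data.frame(time = grid), se = TRUE)
  tcrit <- stats::qt(0.975, pr$df)
  out <- data.frame(time = grid, fd_fit = pr$fit,
                    lower = pr$fit - tcrit * pr$se.fit,
                    upper = pr$fit + tcrit * pr$se.fit)
  structure(out, n_cells = length(traces), span = span, points = pooled,
            loess = fit, class = c("population_curve", "data.frame"))
}

#' Sliding-window slope estimates with significance
#'
#' For every window of three consecutive grid points (two sampling intervals,
#' advancing one point at a time) a linear trend is fitted to the pooled
#' replicate FD values falling inside the window, giving the slope in percent
#' conversion per minute and a two-sided P-value for slope != 0 from the
#' trend coefficient's t statistic. The smooth population curve supplies the
#' window's mean conversion for downstream threshold routing. At this window
#' size a smooth trend term is degenerate to a straight line, so an ordinary
#' linear fit is used.
#'
#' @param curve a `population_curve`.
#' @param traces the conversion traces the curve was fitted from (defaults to
#'   the pooled points stored in the curve).
#' @param window_points number of consecutive grid points per window
#'   (default 3 = two intervals).
#' @param on_fitted if `TRUE`, fit the trend to the loess curve's fitted
#'   values at the replicate time points instead of the raw replicate values
#'   (alternative mode; raw replicates are the default because testing the
#'   smoothed line alone understates uncertainty).
#' @return data.frame of class `window_slopes`: `t_start`, `t_mid`, `t_end`,
#'   `slope`, `p_value`, `mean_conversion`, `n_points`.
#' @export
sliding_window_slopes <- function(curve, traces = NULL, window_points = 3L,
                                  on_fitted = FALSE) {
  stopifnot(inherits(curve, "population_curve"))
  window_points <- check_count(window_points, "window_points", lower = 3L)
  grid <- curve$time
  if (length(grid) < window_points)
    stop_invalid("grid has %d points; need >= %d", length(grid), window_points)
  if (is.null(traces)) {
    pooled <- attr(curve, "points")
  } else {
    traces <- traces[!vapply(traces, is.null, TRUE)]
    pooled <- do.call(rbind, lapply(traces, function(tr)
      data.frame(cell_id = tr$cell_id, time = tr$time_min, fd = tr$fd_percent)))
    pooled <- pooled[is.finite(pooled$fd) & pooled$time >= 0, ]
  }
  if (on_fitted)
    pooled$fd <- stats::predict(attr(curve, "loess"),
                                data.frame(time = pooled$time))
  eps <- 1e-9
  res <- vector("list", length(grid) - window_points + 1L)
  for (i in seq_along(res)) {
    t0 <- grid[i]; t2 <- grid[i + window_points - 1L]
    sub <- pooled[pooled$time >= t0 - eps & pooled$time <= t2 + eps, ]
    if (length(unique(round(sub$time, 9))) < 2L || nrow(sub) < 3L) {
      message(sprintf("window [%g, %g] skipped: fewer than 2 distinct times", t0, t2))
      next
    }
    fit <- stats::lm(fd ~ time, data = sub)
    sm <- stats::coef(summary(fit))
    slope <- sm["time", "Estimate"]
    se <- sm["time", "Std. Error"]
    df <- fit$df.residual
    p <- if (se == 0) 0 else 2 * stats::pt(abs(slope / se), df, lower.tail = FALSE)
    idx <- i:(i + window_points - 1L)
    res[[i]] <- data.frame(t_start = t0, t_mid = grid[i + (window_points - 1L) %/% 2],
                           t_end = t2, slope = slope, p_value = p,
                           mean_conversion = mean(curve$fd_fit[idx]),
                           n_points = nrow(sub))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("window_slopes", "data.frame"))
}

#' Apply the interaction-calling rules to window slopes
#'
#' A window is called as interaction when its trend is significantly positive
#' and steep enough, and the negative control does not itself satisfy the
#' criteria in the same window:
#' * mean conversion below `conversion_threshold` (70%): slope must be at
#'   least `slope_floor` (1 percent conversion per minute, inclusive) with
#'   P < `alpha`;
#' * mean conversion at or above the threshold: any positive slope with
#'   P < `alpha` suffices.
#' Significance stars follow the P < 0.001 / 0.01 / 0.05 convention. Windows
#' whose mean conversion is at or above `caveat_threshold` (80%) are still
#' evaluated but flagged as difficult to interpret.
#'
#' @param slopes `window_slopes` for the bait-prey pair.
#' @param control_slopes `window_slopes` for the non-interacting control on
#'   the same window grid, or `NULL` (veto disabled, with a warning).
#' @param alpha significance level (default 0.05).
#' @param slope_floor minimum slope (percent/min) below the conversion
#'   threshold; the comparison is inclusive.
#' @param conversion_threshold percent conversion separating the two slope
#'   rules (default 70).
#' @param caveat_threshold percent conversion flagged as hard to interpret
#'   (default 80).
#' @return data.frame of class `interaction_calls`: the slope columns plus
#'   `called`, `stars`, `reason`, `flag_caveat`.
#' @export
call_interactions <- function(slopes, control_slopes = NULL, alpha = 0.05,
                              slope_floor = 1, conversion_threshold = 70,
                              caveat_threshold = 80) {
  stopifnot(inherits(slopes, "data.frame"))
  meets <- function(s) {
    ifelse(s$mean_conversion < conversion_threshold,
           s$slope >= slope_floor & s$p_value < alpha,
           s$slope > 0 & s$p_value < alpha)
  }
  crit <- meets(slopes)
  if (is.null(control_slopes)) {
    warning("no negative control supplied: control veto disabled")
    veto <- rep(FALSE, nrow(slopes))
  } else {
    if (nrow(control_slopes) != nrow(slopes) ||
        !isTRUE(all.equal(control_slopes$t_start, slopes$t_start)))
      stop_invalid("control windows do not match the bait window grid")
    veto <- meets(control_slopes)
  }
  called <- crit & !veto
  reason <- ifelse(called, ifelse(slopes$mean_conversion < conversion_threshold,
                                  "slope>=floor", "positive-above-threshold"),
                   ifelse(crit & veto, "control-veto",
                          ifelse(slopes$p_value >= alpha, "not-significant",
                                 "below-slope-floor")))
  reason[!crit & !(slopes$p_value >= alpha) &
           slopes$mean_conversion >= conversion_threshold &
           slopes$slope <= 0] <- "non-positive-slope"
  out <- cbind(as.data.frame(slopes),
               called = called,
               stars = ifelse(called, significance_stars(slopes$p_value), "none"),
               reason = reason,
               flag_caveat = slopes$mean_conversion >= caveat_threshold)
  structure(out, class = c("interaction_calls", "data.frame"))
}

#' Assemble phase-partitioned interaction profiles
#'
#' Collects per-pair interaction calls into the matrix form used for
#' reporting: one row per bait-prey pair, windows partitioned by phase, and
#' adjacent called windows merged into contiguous interaction intervals.
#'
#' @param calls named list of `interaction_calls`, one per prey.
#' @param phase_boundaries named list of phase `c(start, end)` intervals
#'   (half-open) used to partition windows by their midpoint.
#' @return object of class `interaction_profile`: list with `calls` (long
#'   data.frame including `pair` and `phase`) and `intervals` (merged called
#'   intervals per pair).
#' @export
build_profile <- function(calls, phase_boundaries = NULL) {
  if (inherits(calls, "interaction_calls")) calls <- list(pair1 = calls)
  long <- do.call(rbind, lapply(names(calls), function(nm) {
    cbind(pair = nm, as.data.frame(calls[[nm]]))
  }))
  long$phase <- NA_character_
  if (!is.null(phase_boundaries) && length(phase_boundaries)) {
    pb <- validate_phase_boundaries(phase_boundaries, Inf)
    for (ph in names(pb)) {
      b <- pb[[ph]]
      long$phase[long$t_mid >= b[1] & long$t_mid < b[2]] <- ph
    }
  }
  intervals <- do.call(rbind, lapply(names(calls), function(nm) {
    cc <- calls[[nm]]
    merge_called_windows(cc, nm)
  }))
  structure(list(calls = long, intervals = intervals),
            class = "interaction_profile")
}

# merge runs of adjacent called windows into contiguous intervals
merge_called_windows <- function(cc, pair) {
  idx <- which(cc$called)
  if (!length(idx))
    return(data.frame(pair = character(), t_start = numeric(),
                      t_end = numeric(), n_windows = integer()))
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  do.call(rbind, lapply(runs, function(r) {
    data.frame(pair = pair, t_start = cc$t_start[r[1]],
               t_end = cc$t_end[r[length(r)]], n_windows = length(r))
  }))
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat("Interaction profile\n")
  if (nrow(x$intervals)) {
    for (i in seq_len(nrow(x$intervals)))
      cat(sprintf("  %s: interaction %g-%g min (%d windows)\n",
                  x$intervals$pair[i], x$intervals$t_start[i],
                  x$intervals$t_end[i], x$intervals$n_windows[i]))
  } else cat("  no interactions called\n")
  invisible(x)
}

#' Score interaction calls against simulated ground truth
#'
#' Compares per-window calls with the cleavage-active windows a simulation
#' was generated from. A window's truth label is positive when its midpoint
#' falls inside a true interaction window. Windows whose midpoint lies within
#' `boundary_tolerance` minutes of a truth boundary are excluded from the
#' confusion counts: with finite sampling and a reporter-degradation lag,
#' calls at a boundary are ambiguous by construction.
#'
#' @param calls an `interaction_calls` data.frame.
#' @param true_windows data.frame with `start`, `end` (minutes), e.g.
#'   `schedule$windows`.
#' @param boundary_tolerance exclusion half-width around truth boundaries,
#'   minutes; defaults to one window width (two sampling intervals) inferred
#'   from the call grid.
#' @return list with the confusion counts (`tp`, `fp`, `fn`, `tn`),
#'   `precision`, `recall`, `f1`, `n_scored`.
#' @export
recover_schedule_benchmark <- function(calls, true_windows,
                                       boundary_tolerance = NULL) {
  mid <- calls$t_mid
  if (is.null(boundary_tolerance))
    boundary_tolerance <- stats::median(calls$t_end - calls$t_start)
  truth <- rep(FALSE, length(mid))
  near_edge <- rep(FALSE, length(mid))
  if (!is.null(true_windows) && nrow(true_windows)) {
    for (i in seq_len(nrow(true_windows))) {
      a <- true_windows$start[i]; b <- true_windows$end[i]
      truth <- truth | (mid >= a & mid < b)
      near_edge <- near_edge | abs(mid - a) < boundary_tolerance |
        abs(mid - b) < boundary_tolerance
    }
  }
  keep <- !near_edge
  tp <- sum(calls$called[keep] & truth[keep])
  fp <- sum(calls$called[keep] & !truth[keep])
  fn <- sum(!calls$called[keep] & truth[keep])
  tn <- sum(!calls$called[keep] & !truth[keep])
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else if (tp + fp + fn == 0) 1 else 0
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f1 = f1, n_scored = sum(keep))
}
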