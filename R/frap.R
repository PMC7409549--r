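# FRAP: simulation, double normalization, one-phase association fitting,
# and normality-routed group comparison.

#' Configuration for a simulated FRAP experiment
#'
#' @param rate_k recovery rate constant, per second (> 0).
#' @param mobile_fraction fraction of the bleached signal that recovers,
#'   in `(0, 1]`.
#' @param prebleach_frames frames acquired before the bleach (default 4).
#' @param bleach_depth fraction of the pre-bleach ROI signal removed by the
#'   bleach pulse, in `(0, 1]`.
#' @param frame_interval frame spacing in seconds (default 0.9).
#' @param n_frames post-bleach frames.
#' @param acquisition_bleach fractional whole-cell signal loss per acquired
#'   frame; affects ROI and reference alike, and is what the reference-ratio
#'   step of double normalization corrects.
#' @param noise_sd Gaussian measurement noise on the ROI reading, expressed in
#'   normalized units (fractions of the bleached span, i.e. of the pre-bleach
#'   minus first post-bleach level). The reference is a whole-cell average
#'   over many pixels and is treated as noise-free.
#' @param seed integer seed.
#' @return object of class `frap_sim_config`.
#' @export
frap_sim_config <- function(rate_k = log(2) / 8.82, mobile_fraction = 1,
                            prebleach_frames = 4L, bleach_depth = 0.8,
                            frame_interval = 0.9, n_frames = 100L,
                            acquisition_bleach = 0.002, noise_sd = 0,
                            seed = 1L) {
  check_number(rate_k, "rate_k", lower = 0, lower_open = TRUE)
  check_number(mobile_fraction, "mobile_fraction", lower = 0, lower_open = TRUE,
               upper = 1)
  prebleach_frames <- check_count(prebleach_frames, "prebleach_frames")
  check_number(bleach_depth, "bleach_depth", lower = 0, lower_open = TRUE,
               upper = 1)
  check_number(frame_interval, "frame_interval", lower = 0, lower_open = TRUE)
  n_frames <- check_count(n_frames, "n_frames", lower = 2L)
  check_number(acquisition_bleach, "acquisition_bleach", lower = 0, upper = 1,
               upper_open = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(rate_k = rate_k, mobile_fraction = mobile_fraction,
                 prebleach_frames = prebleach_frames,
                 bleach_depth = bleach_depth, frame_interval = frame_interval,
                 n_frames = n_frames, acquisition_bleach = acquisition_bleach,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "frap_sim_config")
}

#' Simulate a FRAP trace
#'
#' Pre-bleach frames at a steady level, an instantaneous bleach removing
#' `bleach_depth` of the ROI signal, then single-exponential recovery
#' `F(t) = F_post + (F_plateau - F_post) (1 - exp(-k t))` with the plateau set
#' by the mobile fraction. Acquisition photobleaching dims ROI and reference
#' together frame by frame; Gaussian noise is added to both readings.
#'
#' @param config a [frap_sim_config()].
#' @param cell_id,group labels stored in the output.
#' @return data.frame of class `frap_trace`: `cell_id`, `group`, `time_s`
#'   (0 at the first post-bleach frame; pre-bleach frames negative), `roi`,
#'   `reference`, `prebleach_flag`.
#' @export
simulate_frap_trace <- function(config, cell_id = "cell1", group = "group1") {
  stopifnot(inherits(config, "frap_sim_config"))
  npre <- config$prebleach_frames
  dt <- config$frame_interval
  t_post <- (seq_len(config$n_frames) - 1L) * dt
  t_pre <- -rev(seq_len(npre)) * dt
  f0 <- 1
  f_post <- (1 - config$bleach_depth) * f0
  plateau <- f_post + config$mobile_fraction * (f0 - f_post)
  roi <- c(rep(f0, npre),
           f_post + (plateau - f_post) * (1 - exp(-config$rate_k * t_post)))
  ref <- rep(1, npre + config$n_frames)
  acq <- (1 - config$acquisition_bleach)^(seq_along(roi) - 1L)
  roi <- roi * acq
  ref <- ref * acq
  set.seed(config$seed)
  if (config$noise_sd > 0) {
    # noise_sd is in normalized units: scale by the bleached span
    roi <- roi + stats::rnorm(length(roi), 0,
                              config$noise_sd * (f0 - f_post)) * acq
  }
  structure(data.frame(cell_id = cell_id, group = group,
                       time_s = c(t_pre, t_post), roi = roi, reference = ref,
                       prebleach_flag = c(rep(TRUE, npre),
                                          rep(FALSE, config$n_frames)),
                       stringsAsFactors = FALSE),
            class = c("frap_trace", "data.frame"))
}

#' Double-normalize a FRAP trace
#'
#' Step 1: divide the ROI signal by the reference signal at every frame,
#' correcting acquisition photobleaching. Step 2: full-scale normalization —
#' rescale so the pre-bleach mean of the ratio is 1 and the first post-bleach
#' frame is 0.
#'
#' @param trace a `frap_trace` (columns `time_s`, `roi`, `reference`,
#'   `prebleach_flag`).
#' @param min_bleach_drop minimum fractional drop of the ratio from the
#'   pre-bleach mean to the first post-bleach frame; traces dropping less are
#'   rejected ("no bleach detected").
#' @return data.frame `time_s`, `normalized`, `prebleach_flag`, with
#'   attribute `flags` (character vector, e.g. recovery overshooting the
#'   pre-bleach level).
#' @export
double_normalize <- function(trace, min_bleach_drop = 0.1) {
  stopifnot(all(c("time_s", "roi", "reference", "prebleach_flag") %in%
                  names(trace)))
  if (any(diff(trace$time_s) <= 0))
    stop_invalid("frame times must be strictly increasing")
  if (!any(trace$prebleach_flag))
    stop_invalid("trace has no pre-bleach frames")
  if (any(trace$reference <= 0))
    stop_invalid("trace rejected: non-positive reference frame")
  ratio <- trace$roi / trace$reference
  pre <- mean(ratio[trace$prebleach_flag])
  first_post <- which(!trace$prebleach_flag)[1]
  f0 <- ratio[first_post]
  if ((pre - f0) / pre < min_bleach_drop)
    stop_invalid("trace rejected: no bleach detected")
  normalized <- (ratio - f0) / (pre - f0)
  flags <- character()
  if (any(normalized[!trace$prebleach_flag] > 1 + 1e-8))
    flags <- c(flags, "post-bleach value above pre-bleach mean")
  structure(data.frame(time_s = trace$time_s, normalized = normalized,
                       prebleach_flag = trace$prebleach_flag),
            flags = flags)
}

#' Fit the one-phase association recovery model
#'
#' Nonlinear least squares of the one-phase association curve
#' `F(t) = Y0 + (P - Y0) (1 - exp(-k t))` to the post-bleach frames of a
#' double-normalized trace, with t = 0 at the first post-bleach frame. The
#' baseline `Y0` is a free parameter (it absorbs measurement noise in the
#' frame the normalization is anchored to); the plateau `P` estimates the
#' mobile fraction; the recovery half-time is `t_half = ln 2 / k`. Initial
#' values are taken from a small multistart grid over the rate and the best
#' converged fit is kept.
#'
#' @param normalized output of [double_normalize()] (or any data.frame with
#'   `time_s`, `normalized`, `prebleach_flag`).
#' @param cell_id,group labels carried into the result.
#' @return object of class `frap_fit`: list with `rate_k` (per s), `t_half`
#'   (s), `plateau`, `baseline`, `rms`, `converged`, `n_frames`, `data`,
#'   labels.
#' @export
fit_one_phase <- function(normalized, cell_id = "cell1", group = "group1") {
  post <- normalized[!normalized$prebleach_flag, , drop = FALSE]
  if (nrow(post) < 6)
    stop_invalid("need >= 6 post-bleach frames (got %d)", nrow(post))
  t <- post$time_s - post$time_s[1]
  y <- post$normalized
  span <- max(t[t > 0])
  p0 <- max(stats::median(utils::tail(y, 5)), 0.1)
  kgrid <- log(2) / (span * c(0.02, 0.05, 0.1, 0.25, 0.5, 1))
  best <- NULL
  for (k0 in kgrid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ Y0 + (P - Y0) * (1 - exp(-k * t)),
                        start = list(Y0 = 0, P = p0, k = k0),
                        lower = c(Y0 = -1, P = 0, k = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(rate_k = NA_real_, t_half = NA_real_,
                          plateau = NA_real_, baseline = NA_real_,
                          rms = NA_real_, converged = FALSE,
                          n_frames = nrow(post), data = normalized,
                          cell_id = cell_id, group = group),
                     class = "frap_fit"))
  }
  cf <- stats::coef(best$fit)
  structure(list(rate_k = unname(cf["k"]),
                 t_half = log(2) / unname(cf["k"]),
                 plateau = unname(cf["P"]),
                 baseline = unname(cf["Y0"]),
                 rms = sqrt(best$rss / nrow(post)),
                 converged = TRUE, n_frames = nrow(post),
                 data = normalized, cell_id = cell_id, group = group),
            class = "frap_fit")
}

#' Simulate, normalize and fit one FRAP trace in one call
#'
#' @param config a [frap_sim_config()].
#' @param ... passed to [simulate_frap_trace()].
#' @return a `frap_fit`.
#' @export
frap_roundtrip <- function(config, ...) {
  tr <- simulate_frap_trace(config, ...)
  fit_one_phase(double_normalize(tr), cell_id = tr$cell_id[1],
                group = tr$group[1])
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("FRAP fit for %s: did not converge\n", x$cell_id))
    return(invisible(x))
  }
  cat(sprintf("FRAP one-phase association fit for %s (%s)\n", x$cell_id, x$group))
  cat(sprintf("  k = %.4g /s, t_1/2 = %.3g s, mobile fraction = %.3g (RMS %.3g)\n",
              x$rate_k, x$t_half, x$plateau, x$rms))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(rate_k = object$rate_k, plateau = object$plateau, t_half = object$t_half)
}

#' @export
predict.frap_fit <- function(object, newtimes = NULL, ...) {
  post <- object$data[!object$data$prebleach_flag, ]
  if (is.null(newtimes)) newtimes <- post$time_s - post$time_s[1]
  object$baseline + (object$plateau - object$baseline) *
    (1 - exp(-object$rate_k * newtimes))
}

#' @export
residuals.frap_fit <- function(object, ...) {
  post <- object$data[!object$data$prebleach_flag, ]
  post$normalized - predict(object)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$data$time_s, x$data$normalized, pch = 16, cex = 0.6,
                 xlab = "time (s)", ylab = "normalized fluorescence", ...)
  post <- x$data[!x$data$prebleach_flag, ]
  tt <- seq(0, max(post$time_s - post$time_s[1]), length.out = 200)
  graphics::lines(post$time_s[1] + tt, predict(x, tt), col = "firebrick", lwd = 2)
  graphics::abline(h = c(0, 1), lty = 3, col = "grey60")
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness (D'Agostino's transformation)
#' and kurtosis (Anscombe-Glynn transformation) into
#' `K2 = Z(g1)^2 + Z(g2)^2`, referred to a chi-squared distribution with 2
#' degrees of freedom. Requires n >= 8 for the kurtosis approximation.
#'
#' @param x numeric vector, n >= 8.
#' @return `htest`-like list with `statistic` (K2), `p.value`, `method`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop_invalid("D'Agostino-Pearson test requires n >= 8 (got %d)", n)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness: D'Agostino (1970) normalizing transformation
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zg1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  Zg2 <- ((1 - 2 / (9 * A)) -
            ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zg1^2 + Zg2^2
  structure(list(statistic = c(K2 = K2),
                 p.value = stats::pchisq(K2, 2, lower.tail = FALSE),
                 method = "D'Agostino-Pearson omnibus normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' Normality-routed comparison of FRAP parameter groups
#'
#' Each group's values (by default the fitted half-times) are first checked
#' for normality with the D'Agostino-Pearson omnibus test. Two groups are
#' compared with an unpaired t test when both pass (P >= `normality_alpha`),
#' otherwise with a Mann-Whitney U test; more than two groups with one-way
#' ANOVA when all pass, otherwise Kruskal-Wallis. Groups smaller than eight
#' cannot be assessed for normality and are routed to the rank-based tests.
#'
#' @param fits list of `frap_fit` objects, or a data.frame with columns
#'   `group` and `value`.
#' @param value for a list of fits, which coefficient to compare
#'   (`"t_half"`, `"rate_k"` or `"plateau"`).
#' @param normality_alpha level for the normality pre-test.
#' @return object of class `frap_comparison`: per-group n, mean, SEM and
#'   normality P, the routed `test` name, its `p.value` and `stars`.
#' @export
compare_groups <- function(fits, value = "t_half", normality_alpha = 0.05) {
  if (is.data.frame(fits)) {
    df <- fits[c("group", "value")]
  } else {
    fits <- Filter(function(f) isTRUE(f$converged), fits)
    df <- data.frame(group = vapply(fits, function(f) f$group, ""),
                     value = vapply(fits, function(f) f[[value]], 0))
  }
  df <- df[is.finite(df$value), ]
  counts <- table(df$group)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    warning(sprintf("groups excluded (n < 3): %s", paste(small, collapse = ", ")))
    df <- df[!df$group %in% small, ]
  }
  groups <- split(df$value, df$group)
  if (length(groups) < 2)
    stop_invalid("need at least 2 groups with n >= 3")
  norm_p <- vapply(groups, function(g) {
    if (length(g) < 8) NA_real_ else dagostino_pearson_test(g)$p.value
  }, 0)
  all_normal <- all(!is.na(norm_p) & norm_p >= normality_alpha)
  if (length(groups) == 2) {
    if (all_normal) {
      ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      test <- "t test"
    } else {
      ht <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE)
      test <- "Mann-Whitney U test"
    }
  } else {
    if (all_normal) {
      ht <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
      test <- "one-way ANOVA"
    } else {
      ht <- stats::kruskal.test(value ~ group, data = df)
      test <- "Kruskal-Wallis ANOVA"
    }
  }
  summary_tab <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 0L),
    mean = vapply(groups, mean, 0),
    sem = vapply(groups, function(g) stats::sd(g) / sqrt(length(g)), 0),
    normality_p = norm_p,
    normal = !is.na(norm_p) & norm_p >= normality_alpha
  )
  rownames(summary_tab) <- NULL
  structure(list(groups = summary_tab, test = test,
                 statistic = unname(ht$statistic), p.value = ht$p.value,
                 stars = significance_stars(ht$p.value), value = value),
            class = "frap_comparison")
}

#' @export
print.frap_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s\n", x$value))
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %s: n = %d, %.3g +/- %.2g (SEM)%s\n",
                x$groups$group[i], x$groups$n[i], x$groups$mean[i],
                x$groups$sem[i],
                if (isTRUE(x$groups$normal[i])) "" else " [non-normal]"))
  star <- if (x$stars == "none") "n.s." else x$stars
  cat(sprintf("  %s: P = %.3g (%s)\n", x$test, x$p.value, star))
  invisible(x)
}
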