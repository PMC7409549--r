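# The standard synthetic benchmark: fixed study conditions under which the
# pipeline's window recovery and false-call rate are evaluated.

#' Standard benchmark conditions
#'
#' Returns the fixed configuration used throughout the package to validate
#' interaction calling: 20 cells sampled every 2 minutes over a 115-minute
#' recording with moderate measurement noise, one true interaction window in
#' each measurement phase, and 1-minute fusion-time jitter. See the vignette
#' for the rationale behind each value.
#'
#' @param n_cells number of cells (default 20).
#' @param null if `TRUE`, remove all interaction windows (cleavage never
#'   switches on) — the negative-control / false-positive condition.
#' @return list with `config` ([reporter_kinetics_config()]), `schedule`
#'   ([interaction_schedule()]), `n_cells`, `fusion_jitter_sd`.
#' @export
standard_benchmark <- function(n_cells = 20, null = FALSE) {
  windows <- if (null) list() else list(
    c(6, 18, "PCDI"),
    c(44, 56, "PCDII"),
    c(100, 110, "PCDIII")
  )
  list(
    config = reporter_kinetics_config(),
    schedule = interaction_schedule(windows = windows),
    n_cells = n_cells,
    fusion_jitter_sd = 1
  )
}

#' Run the window-recovery benchmark
#'
#' Simulates the standard benchmark population, runs the full pipeline
#' (quantification, loess, sliding-window slopes, calling with a simulated
#' no-interaction control population as the negative control) and scores the
#' calls against the true interaction windows.
#'
#' @param seed integer master seed.
#' @param n_cells cells per population.
#' @param with_control simulate and use a null population as negative
#'   control (default TRUE).
#' @return list with the `spliff_fit`, the ground-truth windows, and the
#'   confusion summary from [recover_schedule_benchmark()].
#' @export
run_recovery_benchmark <- function(seed = 1L, n_cells = 20,
                                   with_control = TRUE) {
  bench <- standard_benchmark(n_cells = n_cells)
  seeds <- derive_seeds(seed, 2L)
  pop <- simulate_population(bench$config, bench$schedule,
                             n_cells = bench$n_cells,
                             fusion_jitter_sd = bench$fusion_jitter_sd,
                             seed = seeds[1])
  control <- NULL
  if (with_control) {
    nullbench <- standard_benchmark(n_cells = n_cells, null = TRUE)
    control <- simulate_population(nullbench$config, nullbench$schedule,
                                   n_cells = nullbench$n_cells,
                                   fusion_jitter_sd = nullbench$fusion_jitter_sd,
                                   seed = seeds[2])
  }
  fit <- spliff(pop, control_traces = control)
  score <- recover_schedule_benchmark(fit$calls, bench$schedule$windows)
  list(fit = fit, true_windows = bench$schedule$windows, score = score)
}

#' False-call rate on null simulations
#'
#' Simulates `n_replicates` independent populations with cleavage switched
#' off, runs the calling pipeline on each (without a control, so no veto can
#' mask false positives), and reports the overall fraction of windows called.
#' Under the null this fraction should not exceed the nominal per-window
#' level alpha (the slope-floor rule makes it conservative).
#'
#' @param seed integer master seed.
#' @param n_replicates number of independent null populations.
#' @param n_cells cells per population (default 10).
#' @param alpha per-window significance level.
#' @return list with `false_call_rate`, `n_windows`, `n_called`, `alpha`,
#'   and the binomial standard error of alpha at this window count.
#' @export
null_false_call_rate <- function(seed = 1L, n_replicates = 200, n_cells = 10,
                                 alpha = 0.05) {
  bench <- standard_benchmark(n_cells = n_cells, null = TRUE)
  seeds <- derive_seeds(seed, n_replicates)
  n_called <- 0L
  n_windows <- 0L
  for (r in seq_len(n_replicates)) {
    pop <- simulate_population(bench$config, bench$schedule,
                               n_cells = bench$n_cells,
                               fusion_jitter_sd = bench$fusion_jitter_sd,
                               seed = seeds[r])
    fit <- suppressWarnings(spliff(pop, control_traces = NULL, alpha = alpha))
    n_called <- n_called + sum(fit$calls$called)
    n_windows <- n_windows + nrow(fit$calls)
  }
  se <- sqrt(alpha * (1 - alpha) / n_windows)
  list(false_call_rate = n_called / n_windows, n_windows = n_windows,
       n_called = n_called, alpha = alpha, binomial_se = se)
}
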