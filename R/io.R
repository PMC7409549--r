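# Plain-text input/output: long-format CSV schemas and YAML configuration.

intensity_cols <- c("cell_id", "time_min", "channel", "roi", "cytosol",
                    "background", "prefusion_flag")
frap_cols <- c("cell_id", "group", "time_s", "roi", "reference",
               "prebleach_flag")

check_schema <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_invalid("%s: missing required columns: %s", path,
                 paste(missing, collapse = ", "))
  invisible(df)
}

#' Read long-format intensity measurements
#'
#' Expects columns `cell_id, time_min, channel, roi, cytosol, background,
#' prefusion_flag` (one row per cell, frame and channel; `time_min` relative
#' to cell fusion). Missing timepoints are allowed and stay gaps. Returns one
#' `intensity_trace` per cell.
#'
#' @param path CSV file.
#' @param phase_boundaries optional named list attached to every trace.
#' @return named list of `intensity_trace` data.frames.
#' @export
read_intensity_csv <- function(path, phase_boundaries = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, intensity_cols, path)
  if (!all(df$channel %in% c("red", "green")))
    stop_invalid("%s: channel must be 'red' or 'green' (first bad line: %d)",
                 path, which(!df$channel %in% c("red", "green"))[1] + 1L)
  df$prefusion_flag <- as.logical(df$prefusion_flag)
  lapply(split(df, df$cell_id), function(tr) {
    tr <- tr[order(tr$time_min, tr$channel), ]
    rownames(tr) <- NULL
    structure(tr, phase_boundaries = phase_boundaries,
              class = c("intensity_trace", "data.frame"))
  })
}

#' Write intensity traces to CSV
#'
#' @param traces list of `intensity_trace` (or a `spliff_population`).
#' @param path output CSV file.
#' @export
write_intensity_csv <- function(traces, path) {
  if (inherits(traces, "spliff_population")) traces <- traces$traces
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df[intensity_cols], path, row.names = FALSE)
  invisible(path)
}

#' Write conversion traces to CSV
#'
#' Columns: `cell_id, time_min, rfi_red, rfi_green, fd_percent, phase, flags`
#' where `flags` is a semicolon-joined list (`negative`, `caveat`).
#'
#' @param traces list of `conversion_trace`.
#' @param path output CSV file.
#' @export
write_conversion_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, as.data.frame))
  df$flags <- trimws(paste(ifelse(df$flag_negative, "negative", ""),
                           ifelse(df$flag_caveat, "caveat", "")))
  df$flags <- gsub(" ", ";", df$flags)
  utils::write.csv(df[c("cell_id", "time_min", "rfi_red", "rfi_green",
                        "fd_percent", "phase", "flags")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read FRAP traces from CSV
#'
#' Expects columns `cell_id, group, time_s, roi, reference, prebleach_flag`.
#'
#' @param path CSV file.
#' @return named list of `frap_trace` data.frames, one per cell.
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, frap_cols, path)
  df$prebleach_flag <- as.logical(df$prebleach_flag)
  lapply(split(df, df$cell_id), function(tr) {
    tr <- tr[order(tr$time_s), ]
    rownames(tr) <- NULL
    structure(tr, class = c("frap_trace", "data.frame"))
  })
}

#' Write FRAP traces to CSV
#' @param traces list of `frap_trace`.
#' @param path output CSV file.
#' @export
write_frap_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df[frap_cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Understands the sections `kinetics` (fields of
#' [reporter_kinetics_config()]), `schedule` (fields of
#' [interaction_schedule()], with `windows` as a list of
#' `{start, end, phase}` maps), `population` (`n_cells`,
#' `fusion_jitter_sd`), `analysis` (`span`, `alpha`, `slope_floor`,
#' `conversion_threshold`, `caveat_threshold`, `window_points`) and `frap`
#' (fields of [frap_sim_config()]). Missing sections fall back to defaults.
#'
#' @param path YAML file.
#' @return list with constructed `config`, `schedule` and the raw `analysis`,
#'   `population` and `frap` parameter lists.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config <- do.call(reporter_kinetics_config,
                    raw$kinetics %||% list())
  sched_args <- raw$schedule %||% list()
  if (!is.null(sched_args$windows)) {
    sched_args$windows <- lapply(sched_args$windows, function(w)
      c(w$start, w$end, w$phase %||% NA_character_))
  }
  schedule <- do.call(interaction_schedule, sched_args)
  frap <- if (is.null(raw$frap)) NULL else do.call(frap_sim_config, raw$frap)
  list(config = config, schedule = schedule,
       population = raw$population %||% list(),
       analysis = raw$analysis %||% list(),
       frap = frap, raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable hash of a configuration for run manifests: serialize deterministic
# fields to a canonical string and fold with a polynomial rolling hash
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15)), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
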