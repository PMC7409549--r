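#' @keywords internal
"_PACKAGE"

# shared validation helpers ----------------------------------------------

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a single finite number", name)
  if (x < lower || (lower_open && x <= lower))
    stop_invalid("'%s' must be %s %s", name, if (lower_open) ">" else ">=", lower)
  if (x > upper || (upper_open && x >= upper))
    stop_invalid("'%s' must be %s %s", name, if (upper_open) "<" else "<=", upper)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower)
    stop_invalid("'%s' must be an integer >= %d", name, lower)
  invisible(as.integer(x))
}

#' Map a P-value to the conventional significance stars
#'
#' Categories follow the usual convention: `***` for P < 0.001, `**` for
#' P < 0.01, `*` for P < 0.05, and `"none"` otherwise.
#'
#' @param p numeric vector of P-values.
#' @return character vector of the same length.
#' @export
significance_stars <- function(p) {
  out <- rep("none", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- "none"
  out
}

# Derive a stream of reproducible child seeds from one user seed, keeping
# every value inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
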