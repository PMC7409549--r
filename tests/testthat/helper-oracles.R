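# Independent oracles used across the suite. These are deliberately written
# from scratch (closed forms, explicit normal equations) and never call the
# code paths they check.

# (exp(x t) - 1)/x with its x -> 0 limit, numerically safe
phi_fn <- function(x, t) {
  if (abs(x) < 1e-12) t else expm1(x * t) / x
}

# Closed-form solution of
#   U' = s - (k + d_r) U, R' = k U - d_r R, G' = k U - d_g G
# over one segment of length t with constant rates, from (U0, R0, G0).
analytic_segment <- function(state, t, s, k, d_r, d_g) {
  a <- k + d_r
  if (abs(a) < 1e-12) {
    U <- function(tt) state[1] + s * tt
    c1 <- NA; c2 <- NA
  }
  Ut <- if (abs(a) < 1e-12) state[1] + s * t else
    s / a + (state[1] - s / a) * exp(-a * t)
  conv_integral <- function(d) {
    # exp(-d t) * Int_0^t exp(d tau) U(tau) dtau
    if (abs(a) < 1e-12) {
      # U linear in tau
      I <- state[1] * phi_fn(d, t) +
        s * (if (abs(d) < 1e-12) t^2 / 2 else (t * exp(d * t) - phi_fn(d, t)) / d)
      return(exp(-d * t) * I)
    }
    c1 <- s / a
    c2 <- state[1] - s / a
    exp(-d * t) * (c1 * phi_fn(d, t) + c2 * phi_fn(d - a, t))
  }
  Rt <- exp(-d_r * t) * state[2] + k * conv_integral(d_r)
  Gt <- exp(-d_g * t) * state[3] + k * conv_integral(d_g)
  c(Ut, Rt, Gt)
}

# Analytic trajectory for a full schedule, evaluated at sorted times >= 0.
analytic_trajectory <- function(config, schedule, times) {
  win <- schedule$windows
  breaks <- sort(unique(c(0, schedule$total_duration, win$start, win$end)))
  k_of <- function(t) {
    k <- config$cleavage_rate_off
    if (nrow(win)) {
      for (i in seq_len(nrow(win)))
        if (t >= win$start[i] && t < win$end[i]) k <- config$cleavage_rate_on
    }
    k
  }
  state <- c(config$initial_reporter, 0, 0)
  out <- matrix(NA_real_, length(times), 3)
  seg_start <- breaks[-length(breaks)]
  seg_end <- breaks[-1]
  t0 <- 0
  for (i in seq_along(seg_start)) {
    a <- seg_start[i]; b <- seg_end[i]
    k <- k_of((a + b) / 2)
    inside <- which(times > a & times <= b)
    for (j in inside) {
      out[j, ] <- analytic_segment(state, times[j] - a, config$synthesis_rate,
                                   k, config$reporter_degradation_rate,
                                   config$gfp_degradation_rate)
    }
    state <- analytic_segment(state, b - a, config$synthesis_rate, k,
                              config$reporter_degradation_rate,
                              config$gfp_degradation_rate)
  }
  out[times == 0, ] <- rep(c(config$initial_reporter, 0, 0),
                           each = sum(times == 0))
  colnames(out) <- c("U", "R_c", "G_c")
  out
}

# Brute-force loess oracle: tricube-weighted quadratic least squares via the
# normal equations at each evaluation point.
loess_oracle <- function(x, y, span, grid) {
  n <- length(x)
  q <- floor(span * n)
  vapply(grid, function(x0) {
    d <- abs(x - x0)
    dq <- sort(d)[q]
    w <- pmax(1 - (d / dq)^3, 0)^3
    ok <- w > 0
    X <- cbind(1, x[ok] - x0, (x[ok] - x0)^2)
    beta <- solve(t(X) %*% (w[ok] * X), t(X) %*% (w[ok] * y[ok]))
    beta[1]
  }, 0)
}

# Closed-form OLS slope and two-sided t-test P-value from the normal equations
ols_oracle <- function(t, y) {
  n <- length(t)
  tb <- mean(t); yb <- mean(y)
  sxx <- sum((t - tb)^2)
  slope <- sum((t - tb) * (y - yb)) / sxx
  intercept <- yb - slope * tb
  res <- y - intercept - slope * t
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- slope / se
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  list(slope = slope, se = se, p = p)
}

# small noiseless study setup used by several tests
quiet_config <- function(...) {
  reporter_kinetics_config(noise_sd = 0, background_level = 0,
                           bleach_per_exposure_red = 0,
                           bleach_per_exposure_green = 0, ...)
}
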