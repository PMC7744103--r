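# Internal numerical helpers shared across modules.

# Sampling interval (ms) of a uniform time grid; errors on irregular grids.
grid_dt <- function(time_ms, tol = 1e-6) {
  if (length(time_ms) < 2L) abort("trace needs at least two samples")
  d <- diff(time_ms)
  if (any(d <= 0)) abort("time must be strictly increasing")
  dt <- median(d)
  if (max(abs(d - dt)) > tol * max(dt, 1)) {
    abort("trace is not uniformly sampled")
  }
  dt
}

# Sampling rate in kHz from a trace tibble (attribute wins, grid is fallback).
trace_rate_khz <- function(trace) {
  r <- attr(trace, "sampling_khz")
  if (!is.null(r)) return(r)
  1 / grid_dt(trace$time_ms)
}

# Central-difference derivative (mV/ms) on a uniform grid; one-sided at ends.
central_diff <- function(v, dt) {
  n <- length(v)
  if (n < 3L) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

# Linear interpolation of series y (on grid t) at time t0.
interp_at <- function(t, y, t0) {
  approx(t, y, xout = t0, rule = 2)$y
}

# Last index i in [from, to - 1] with y[i] < level <= y[i + 1] (upward
# crossing), or NA if none.
last_upward_crossing <- function(y, level, from, to) {
  idx <- seq(from, to - 1L)
  hit <- idx[y[idx] < level & y[idx + 1L] >= level]
  if (length(hit) == 0L) return(NA_integer_)
  max(hit)
}

# Interpolated time at which y crosses `level` between samples i and i+1.
crossing_time <- function(t, y, i, level) {
  t[i] + (level - y[i]) / (y[i + 1L] - y[i]) * (t[i + 1L] - t[i])
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    abort(sprintf("`%s` = %g is out of range", name, x))
  }
  invisible(x)
}

new_seeded_rng <- function(seed) {
  if (!is.null(seed)) {
    check_number(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
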