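# Internal helpers: classed conditions and small numeric utilities.

abort_ewt <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ewtflow_error", "error", "condition"),
                      call = call))
}

warn_ewt <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "ewtflow_warning", "warning", "condition")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_number(x))
    abort_ewt(sprintf("`%s` must be a single finite number", name), "invalid_parameter")
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    abort_ewt(sprintf("`%s` = %g is outside the allowed range %s%g, %g%s",
                      name, x,
                      if (strict_lower) "(" else "[", lower, upper,
                      if (strict_upper) ")" else "]"),
              "invalid_parameter")
  invisible(x)
}

# Uniform-grid check used by waveform/signal constructors.
is_uniform_grid <- function(t, rel_tol = 1e-9) {
  if (length(t) < 2L) return(TRUE)
  dt <- diff(t)
  all(dt > 0) && (max(dt) - min(dt)) <= rel_tol * max(abs(dt))
}

# Local maxima of a numeric vector (strictly greater than both neighbours;
# plateaus take their midpoint).  Returns integer indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) {
        idx <- c(idx, as.integer(floor((i + j) / 2)))
        i <- j + 1L
      } else {
        i <- j + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  idx
}

# Linear interpolation of a waveform onto new times, constant extrapolation.
interp_series <- function(t, y, t_new) {
  stats::approx(t, y, xout = t_new, rule = 2)$y
}
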