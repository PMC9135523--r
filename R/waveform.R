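#' Velocity waveform container
#'
#' A uniformly sampled time series of centerline blood velocity over one or
#' more cardiac cycles.  Serves both as simulation ground truth and as the
#' target of velocity estimation.
#'
#' @param time Time stamps in seconds; strictly increasing, uniform step.
#' @param velocity Velocities in m/s, same length as `time`.
#' @param heart_rate Heart rate in beats/min, or `NA` if unknown.
#'
#' @return An object of class `velocity_waveform` (a list with elements
#'   `time`, `velocity`, `heart_rate`, `sample_rate`).
#' @export
velocity_waveform <- function(time, velocity, heart_rate = NA_real_) {
  if (length(time) < 2L)
    abort_ewt("a velocity waveform needs at least 2 samples", "invalid_parameter")
  if (length(time) != length(velocity))
    abort_ewt("`time` and `velocity` must have the same length", "invalid_parameter")
  if (!all(is.finite(time)) || !all(is.finite(velocity)))
    abort_ewt("waveform values must be finite", "invalid_parameter")
  if (!is_uniform_grid(time))
    abort_ewt("`time` must be strictly increasing with a uniform step", "invalid_parameter")
  structure(list(time = as.numeric(time), velocity = as.numeric(velocity),
                 heart_rate = as.numeric(heart_rate),
                 sample_rate = 1 / mean(diff(time))),
            class = "velocity_waveform")
}

#' @export
print.velocity_waveform <- function(x, ...) {
  cat(sprintf("<velocity_waveform> %d samples @ %.6g Hz, %.3g-%.3g s, v in [%.4g, %.4g] m/s%s\n",
              length(x$time), x$sample_rate, min(x$time), max(x$time),
              min(x$velocity), max(x$velocity),
              if (is.na(x$heart_rate)) "" else sprintf(", HR %g bpm", x$heart_rate)))
  invisible(x)
}

#' Parametric pulsatile umbilical-artery velocity waveform
#'
#' Generates a periodic centerline velocity waveform parameterised by peak
#' systolic velocity (VS), end-diastolic velocity (VD), heart rate and a
#' systolic-fraction shape parameter.  Within each cardiac cycle, a
#' raised-cosine systolic bump of relative width `sys_frac` rises from VD to
#' VS and returns; the remainder of the cycle stays at the diastolic level.
#' This is a documented stand-in for clinical umbilical waveforms, whose
#' functional form is unspecified: it reproduces the quantities the
#' downstream indices use (VS, VD, mean velocity = VD + sys_frac/2 * (VS-VD))
#' without claiming morphological realism.
#'
#' The default heart rate of 145 beats/min is a typical fetal heart rate.
#'
#' @param vs Peak systolic velocity in m/s (`vs >= vd`).
#' @param vd End-diastolic velocity in m/s (`vd >= 0`).
#' @param heart_rate Heart rate in beats/min.
#' @param duration Waveform duration in s; must cover at least one cycle.
#' @param sample_rate Sampling rate in Hz.
#' @param sys_frac Fraction of the cycle occupied by the systolic bump,
#'   in (0, 1\].  Controls the time-averaged mean velocity.
#'
#' @return A [velocity_waveform].
#' @examples
#' wf <- umbilical_waveform(vs = 0.6, vd = 0.2, heart_rate = 145, duration = 2)
#' range(wf$velocity)
#' @export
umbilical_waveform <- function(vs, vd, heart_rate = 145, duration = 2,
                               sample_rate = 1000, sys_frac = 0.7) {
  check_number(vs, "vs", lower = 0)
  check_number(vd, "vd", lower = 0)
  if (vs < vd)
    abort_ewt(sprintf("vs (%g) must be >= vd (%g)", vs, vd), "invalid_parameter")
  check_number(heart_rate, "heart_rate", lower = 0, strict_lower = TRUE)
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_number(sys_frac, "sys_frac", lower = 0, upper = 1, strict_lower = TRUE)
  period <- 60 / heart_rate
  if (!is_number(duration) || duration <= period)
    abort_ewt(sprintf("duration (%g s) must exceed one cardiac period (%g s)",
                      duration, period), "invalid_parameter")
  t <- seq(0, duration, by = 1 / sample_rate)
  u <- (t / period) %% 1                       # cycle phase in [0, 1)
  s <- ifelse(u < sys_frac, 0.5 * (1 - cos(2 * pi * u / sys_frac)), 0)
  velocity_waveform(t, vd + (vs - vd) * s, heart_rate = heart_rate)
}

#' Parabolic (Poiseuille) cross-vessel flow profile
#'
#' Laminar flow in a cylindrical vessel has the classic parabolic velocity
#' profile \eqn{v(r) = v_c (1 - (r/R)^2)}: centerline velocity at the axis,
#' zero at the wall (no-slip).
#'
#' @param v_center Centerline velocity in m/s.
#' @param r Radial offset from the vessel axis (same unit as `R`).
#' @param R Vessel radius (> 0).
#' @return Velocity at radius `r`, in m/s.  Vectorised over `r`.
#' @examples
#' parabolic_profile(0.4, r = c(0, 1 / sqrt(2), 1), R = 1)
#' @export
parabolic_profile <- function(v_center, r, R) {
  if (!is_number(R) || R <= 0)
    abort_ewt("vessel radius `R` must be a single positive number", "invalid_parameter")
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0) || any(r > R))
    abort_ewt("radial offset `r` must satisfy 0 <= r <= R", "invalid_parameter")
  v_center * (1 - (r / R)^2)
}
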