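#' Doppler-shift signal container
#'
#' Holds the real-valued demodulated (audio-band) Doppler-shift signal
#' together with its sampling rate, acquisition geometry and, when produced
#' by the simulator, the ground-truth velocity waveform.
#'
#' @param samples Real-valued sample series.
#' @param sample_rate Sampling rate in Hz.
#' @param geometry A [beam_geometry], or `NULL` when unknown.
#' @param truth Optional [velocity_waveform] ground truth.
#' @return An object of class `doppler_signal`.
#' @export
doppler_signal <- function(samples, sample_rate, geometry = NULL, truth = NULL) {
  if (!is.numeric(samples) || !all(is.finite(samples)))
    abort_ewt("`samples` must be a finite numeric vector", "invalid_parameter")
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  if (!is.null(geometry) && !is_beam_geometry(geometry))
    abort_ewt("`geometry` must be a beam_geometry or NULL", "invalid_parameter")
  if (!is.null(truth) && !inherits(truth, "velocity_waveform"))
    abort_ewt("`truth` must be a velocity_waveform or NULL", "invalid_parameter")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 geometry = geometry, truth = truth),
            class = "doppler_signal")
}

#' @export
print.doppler_signal <- function(x, ...) {
  cat(sprintf("<doppler_signal> %d samples @ %g Hz (%.3g s)%s%s\n",
              length(x$samples), x$sample_rate, length(x$samples) / x$sample_rate,
              if (is.null(x$geometry)) "" else ", with geometry",
              if (is.null(x$truth)) "" else ", with ground truth"))
  invisible(x)
}

#' Simulate a pulsed-wave Doppler echo signal from a velocity waveform
#'
#' Forward model: each of `n_scatterers` blood scatterers moves with a
#' velocity proportional to the centerline waveform and contributes a unit
#' sinusoid whose instantaneous frequency is the Doppler shift
#' \eqn{f_d(t) = 2 v(t) \cos(\alpha) f_0 / c}, with an independent uniform
#' random initial phase.  Under a `"uniform"` profile all scatterers move at
#' the centerline velocity (a small sample volume); under `"parabolic"` each
#' scatterer sits at a random radial position drawn uniformly over the
#' vessel cross-section (density proportional to radius), so its velocity is
#' scaled by the Poiseuille factor \eqn{1 - (r/R)^2}.  White Gaussian noise
#' is added to reach the geometry's `snr_db` (signal power over noise power,
#' in dB); `NA` means noise-free.
#'
#' For an identically zero truth waveform the signal term vanishes; the
#' noise level is then referenced to the power of a unit-amplitude tone
#' (0.5) so the configured SNR still defines a floor.
#'
#' @param truth A [velocity_waveform] of centerline velocity (m/s).
#' @param geometry A [beam_geometry]; its `sample_rate` sets the output grid.
#' @param n_scatterers Number of scatterers (>= 1).
#' @param profile `"uniform"` or `"parabolic"`.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   samples.
#' @return A [doppler_signal] carrying `truth` and `geometry`.
#' @examples
#' wf <- umbilical_waveform(0.6, 0.2, duration = 1.5)
#' sig <- simulate_doppler(wf, beam_geometry(snr_db = 20), seed = 1)
#' @export
simulate_doppler <- function(truth, geometry, n_scatterers = 20,
                             profile = c("uniform", "parabolic"), seed = NULL) {
  if (!inherits(truth, "velocity_waveform"))
    abort_ewt("`truth` must be a velocity_waveform", "invalid_parameter")
  if (!is_beam_geometry(geometry))
    abort_ewt("`geometry` must be a beam_geometry", "invalid_parameter")
  profile <- match.arg(profile)
  if (!is_number(n_scatterers) || n_scatterers < 1)
    abort_ewt("`n_scatterers` must be >= 1", "invalid_parameter")
  n_scatterers <- as.integer(n_scatterers)

  fs <- geometry$sample_rate
  f_peak <- abs(velocity_to_doppler(max(abs(truth$velocity)), geometry))
  if (f_peak >= fs / 2)
    abort_ewt(sprintf(
      "predicted peak Doppler shift %.1f Hz reaches the Nyquist limit %.1f Hz; increase sample_rate",
      f_peak, fs / 2), "aliasing_error")

  t <- seq(0, max(truth$time), by = 1 / fs)
  v <- interp_series(truth$time, truth$velocity, t)
  f_center <- velocity_to_doppler(v, geometry)

  if (!is.null(seed)) set.seed(seed)
  scale <- if (profile == "uniform") rep(1, n_scatterers) else 1 - stats::runif(n_scatterers)
  phase0 <- stats::runif(n_scatterers, 0, 2 * pi)

  x <- numeric(length(t))
  amp <- 1 / sqrt(n_scatterers)
  for (k in seq_len(n_scatterers)) {
    phase <- 2 * pi * cumsum(f_center * scale[k]) / fs + phase0[k]
    x <- x + amp * cos(phase)
  }

  if (!is.na(geometry$snr_db)) {
    p_sig <- mean(x^2)
    if (p_sig == 0) p_sig <- 0.5              # zero-velocity reference power
    noise_sd <- sqrt(p_sig / 10^(geometry$snr_db / 10))
    x <- x + stats::rnorm(length(x), sd = noise_sd)
  }
  doppler_signal(x, fs, geometry = geometry, truth = truth)
}

#' Apply frequency-proportional tissue attenuation
#'
#' Ultrasound amplitude decays exponentially along the propagation path,
#' with an exponent proportional to the carrier frequency:
#' \eqn{W_r = W_0 \exp(-a f_0 r)} where `a` is the tissue attenuation
#' coefficient and `r` the propagation distance.  The received Doppler
#' samples are scaled by this factor; the applied factor is recorded in the
#' returned object's `attenuation_factor` element.
#'
#' @param signal A [doppler_signal] whose geometry supplies \eqn{f_0}.
#' @param a Attenuation coefficient (per Hz per unit distance), >= 0.
#' @param depth Propagation distance, >= 0 (same distance unit as `a`).
#' @return The attenuated [doppler_signal].
#' @export
apply_attenuation <- function(signal, a, depth) {
  if (!inherits(signal, "doppler_signal"))
    abort_ewt("`signal` must be a doppler_signal", "invalid_parameter")
  if (is.null(signal$geometry))
    abort_ewt("attenuation needs the signal's geometry (carrier frequency)", "invalid_parameter")
  check_number(a, "a", lower = 0)
  check_number(depth, "depth", lower = 0)
  factor <- exp(-a * signal$geometry$carrier_freq * depth)
  out <- signal
  out$samples <- signal$samples * factor
  out$attenuation_factor <- factor
  out
}
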