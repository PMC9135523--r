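#' Pulsed-wave Doppler acquisition geometry
#'
#' Bundles the acquisition physics needed to map between blood velocity and
#' Doppler shift: the transducer carrier frequency \eqn{f_0}, the insonation
#' angle between beam and flow, the speed of sound in tissue \eqn{c}, the
#' sampling rate of the demodulated Doppler-shift signal, and the
#' signal-to-noise ratio of the recording.
#'
#' Medical ultrasound carriers lie in roughly 1--10 MHz; abdominal
#' convex-array probes used for umbilical Doppler run at 2.5--5 MHz.  The
#' insonation angle is clinically kept below 60 degrees because the Doppler
#' shift scales with its cosine; larger angles are accepted here with a
#' warning.  Sound speed in soft tissue is conventionally 1540 m/s.
#'
#' @param carrier_freq Carrier (emitted) frequency \eqn{f_0} in Hz.
#'   Must lie in \[1e6, 1e7\].
#' @param angle_deg Insonation angle in degrees, in \[0, 90).  Values of
#'   60 degrees or more trigger a warning (poor clinical practice, valid
#'   geometry).
#' @param sound_speed Speed of sound \eqn{c} in m/s (default 1540).
#' @param sample_rate Sampling rate of the Doppler-shift signal in Hz.
#' @param snr_db Signal-to-noise ratio in dB, or `NA` for a noise-free
#'   recording.
#'
#' @return An object of class `beam_geometry`.
#' @examples
#' beam_geometry(carrier_freq = 3.5e6, angle_deg = 60, sample_rate = 5000)
#' @export
beam_geometry <- function(carrier_freq = 3.5e6, angle_deg = 60,
                          sound_speed = 1540, sample_rate = 5000,
                          snr_db = NA_real_) {
  check_number(carrier_freq, "carrier_freq", lower = 1e6, upper = 1e7)
  check_number(angle_deg, "angle_deg", lower = 0, upper = 90, strict_upper = TRUE)
  check_number(sound_speed, "sound_speed", lower = 0, strict_lower = TRUE)
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  if (!(length(snr_db) == 1L && (is.na(snr_db) || is.finite(snr_db))))
    abort_ewt("`snr_db` must be a single number or NA", "invalid_parameter")
  if (angle_deg >= 60)
    warn_ewt(sprintf("insonation angle %.1f deg is at or above the 60 deg clinical guideline",
                     angle_deg), "clinical_angle")
  structure(list(carrier_freq = carrier_freq, angle_deg = angle_deg,
                 sound_speed = sound_speed, sample_rate = sample_rate,
                 snr_db = as.numeric(snr_db)),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> f0 = %.3g MHz, angle = %.1f deg, c = %g m/s, fs = %g Hz, SNR = %s\n",
              x$carrier_freq / 1e6, x$angle_deg, x$sound_speed, x$sample_rate,
              if (is.na(x$snr_db)) "noise-free" else sprintf("%g dB", x$snr_db)))
  invisible(x)
}

is_beam_geometry <- function(x) inherits(x, "beam_geometry")
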