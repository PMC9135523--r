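# Shared fixtures, all generated in code.

# Multi-tone signal with bin-aligned frequencies (no spectral leakage):
# normalized angular frequencies `freqs_pi` (in units of pi) on a grid of
# length n must give integer FFT bins, i.e. freqs_pi * n / 2 integral.
tone_signal <- function(freqs_pi, n = 640, amps = rep(1, length(freqs_pi))) {
  k <- 0:(n - 1)
  rowSums(vapply(seq_along(freqs_pi),
                 function(i) amps[i] * cos(freqs_pi[i] * pi * k),
                 numeric(n)))
}

default_geometry <- function(snr_db = NA_real_, sample_rate = 5000) {
  suppressWarnings(beam_geometry(carrier_freq = 3.5e6, angle_deg = 60,
                                 sound_speed = 1540, sample_rate = sample_rate,
                                 snr_db = snr_db))
}

# An if_track built directly from known frequency samples (unit amplitude).
track_from_freq <- function(t, freq, amp = rep(1, length(t))) {
  structure(list(time = t, freq = freq, amp = amp,
                 sample_rate = 1 / mean(diff(t)), source_mode = NA_integer_,
                 n_clipped = 0L),
            class = "if_track")
}
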