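# Hilbert analysis of empirical modes: analytic signal, instantaneous
# frequency tracks, frequency principal component, polynomial frequency-law
# fitting, and the Hilbert time-frequency spectrum.

#' Analytic signal (instantaneous amplitude and phase)
#'
#' Computes the analytic signal \eqn{z(t) = x(t) + i H[x](t)} of a real
#' mode via the FFT one-sided-spectrum construction, and returns its
#' modulus (instantaneous amplitude envelope) and unwrapped argument
#' (instantaneous phase).
#'
#' @param mode Real sample series, length >= 8.
#' @param sample_rate Sampling rate in Hz (kept for downstream use).
#' @return A list with elements `amp` (>= 0) and `phase` (unwrapped,
#'   radians), both the length of `mode`.
#' @export
analytic_signal <- function(mode, sample_rate = 1) {
  if (!is.numeric(mode) || length(mode) < 8L)
    abort_ewt("`mode` must be a numeric series of length >= 8", "invalid_parameter")
  n <- length(mode)
  if (all(mode == 0))
    return(list(amp = numeric(n), phase = numeric(n)))
  h <- numeric(n)
  half <- floor(n / 2)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:half] <- 2
    h[half + 1] <- 1
  } else {
    h[2:(half + 1)] <- 2
  }
  z <- stats::fft(stats::fft(mode) * h, inverse = TRUE) / n
  list(amp = Mod(z), phase = as.numeric(signal::unwrap(Arg(z))))
}

#' Instantaneous-frequency track of a mode
#'
#' Differentiates the unwrapped analytic phase: central differences in the
#' interior, one-sided differences at the endpoints, divided by
#' \eqn{2\pi} to give Hz.  Negative values (phase jitter where the
#' amplitude is tiny) are clipped to zero; the number of clipped samples is
#' recorded in the track's `n_clipped` element.
#'
#' @param mode Real sample series, length >= 8.
#' @param sample_rate Sampling rate in Hz.
#' @param source_mode Optional integer tag identifying the mode.
#' @return An object of class `if_track`: list with `time` (s), `freq`
#'   (Hz), `amp`, `sample_rate`, `source_mode`, `n_clipped`.
#' @examples
#' fs <- 2000; t <- seq(0, 1, by = 1 / fs)
#' tr <- instantaneous_frequency(cos(2 * pi * 100 * t), fs)
#' stats::median(tr$freq)
#' @export
instantaneous_frequency <- function(mode, sample_rate, source_mode = NA_integer_) {
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  a <- analytic_signal(mode, sample_rate)
  n <- length(a$phase)
  dphi <- numeric(n)
  dphi[1] <- a$phase[2] - a$phase[1]
  dphi[n] <- a$phase[n] - a$phase[n - 1]
  dphi[2:(n - 1)] <- (a$phase[3:n] - a$phase[1:(n - 2)]) / 2
  freq <- dphi * sample_rate / (2 * pi)
  n_clipped <- sum(freq < 0)
  freq[freq < 0] <- 0
  structure(list(time = (seq_len(n) - 1) / sample_rate, freq = freq,
                 amp = a$amp, sample_rate = sample_rate,
                 source_mode = source_mode, n_clipped = n_clipped),
            class = "if_track")
}

#' @export
print.if_track <- function(x, ...) {
  cat(sprintf("<if_track> %d points @ %g Hz, freq median %.4g Hz, %d negative samples clipped\n",
              length(x$time), x$sample_rate, stats::median(x$freq), x$n_clipped))
  invisible(x)
}

#' Frequency principal component of a set of mode tracks
#'
#' At every instant, selects the instantaneous frequency of the mode whose
#' instantaneous amplitude is largest.  Because additive noise spreads over
#' all bands while the signal concentrates in one, this amplitude-argmax
#' rule follows the physically active band and is little disturbed by
#' noise.  Amplitude ties (including the all-zero case) resolve toward the
#' lower mode index.
#'
#' @param tracks A list of [instantaneous_frequency()] tracks sharing one
#'   time grid.
#' @return An `if_track` whose `freq`/`amp` are the selected values; the
#'   winning mode index per sample is in `mode_index`.
#' @export
principal_component <- function(tracks) {
  if (!is.list(tracks) || length(tracks) == 0L ||
      !all(vapply(tracks, inherits, logical(1), "if_track")))
    abort_ewt("`tracks` must be a non-empty list of if_track objects", "contract_error")
  t0 <- tracks[[1]]$time
  same <- vapply(tracks, function(tr) length(tr$time) == length(t0) &&
                   max(abs(tr$time - t0)) <= 1e-9 * max(t0[length(t0)], 1), logical(1))
  if (!all(same))
    abort_ewt("all tracks must share the same time grid", "contract_error")
  amp <- vapply(tracks, `[[`, numeric(length(t0)), "amp")
  frq <- vapply(tracks, `[[`, numeric(length(t0)), "freq")
  amp <- matrix(amp, nrow = length(t0))
  frq <- matrix(frq, nrow = length(t0))
  winner <- max.col(amp, ties.method = "first")
  idx <- cbind(seq_along(t0), winner)
  structure(list(time = t0, freq = frq[idx], amp = amp[idx],
                 sample_rate = tracks[[1]]$sample_rate,
                 source_mode = NA_integer_, n_clipped = 0L,
                 mode_index = winner),
            class = "if_track")
}

#' Fit a polynomial frequency law to an instantaneous-frequency track
#'
#' Least-squares fit of the model
#' \eqn{F(t) = F_0 + k t + 3 k_n t^2 + e(t)}: an intercept, a linear sweep
#' rate, and a quadratic term whose raw coefficient is reported divided by
#' three (`kn`), keeping a one-to-one mapping to the frequency-law
#' convention this package adopts.  Optionally weights samples by
#' instantaneous amplitude, down-weighting low-amplitude points where phase
#' (hence frequency) is unreliable.
#'
#' @param track An `if_track`.
#' @param order 1 (linear) or 2 (quadratic, default).
#' @param weight_by_amp If `TRUE`, weighted least squares with weights
#'   proportional to the track amplitude.
#' @return An object of class `frequency_law`: list with `f0` (Hz), `k`
#'   (Hz/s), `kn` (Hz/s^2; one third of the raw quadratic coefficient),
#'   `residual_rms` (Hz), `order`.
#' @examples
#' fs <- 500; t <- seq(0, 1, by = 1 / fs)
#' tr <- structure(list(time = t, freq = 50 + 10 * t + 30 * t^2,
#'                      amp = rep(1, length(t)), sample_rate = fs,
#'                      source_mode = NA, n_clipped = 0L), class = "if_track")
#' fit_frequency_law(tr)
#' @export
fit_frequency_law <- function(track, order = 2L, weight_by_amp = FALSE) {
  if (!inherits(track, "if_track"))
    abort_ewt("`track` must be an if_track", "invalid_parameter")
  if (!order %in% c(1L, 2L))
    abort_ewt("`order` must be 1 or 2", "invalid_parameter")
  n <- length(track$time)
  if (n < order + 2L)
    abort_ewt(sprintf("need at least %d points to fit order %d", order + 2L, order),
              "invalid_parameter")
  X <- cbind(1, track$time)
  if (order == 2L) X <- cbind(X, track$time^2)
  if (qr(X)$rank < ncol(X))
    abort_ewt("rank-deficient design: time values do not span the polynomial", "fit_error")
  w <- if (weight_by_amp) track$amp else rep(1, n)
  if (weight_by_amp && all(w == 0)) w <- rep(1, n)
  fit <- stats::lm.wfit(X, track$freq, w = w)
  cf <- fit$coefficients
  structure(list(f0 = cf[[1]], k = cf[[2]],
                 kn = if (order == 2L) cf[[3]] / 3 else 0,
                 residual_rms = sqrt(mean(fit$residuals^2)),
                 order = order),
            class = "frequency_law")
}

#' @export
print.frequency_law <- function(x, ...) {
  cat(sprintf("<frequency_law> F(t) = %.4g + %.4g t + 3*%.4g t^2  (residual rms %.3g Hz)\n",
              x$f0, x$k, x$kn, x$residual_rms))
  invisible(x)
}

#' Hilbert time-frequency spectrum of an empirical mode set
#'
#' Accumulates each mode's squared instantaneous amplitude onto a
#' time-frequency grid at its instantaneous frequency, giving the energy
#' distribution of the signal over the time-frequency plane.  Frequencies
#' beyond the grid are clamped to the edge rows, so the total accumulated
#' energy equals the total squared amplitude of all tracks exactly.
#'
#' @param modes An `ewt_modes` object from [ewt_decompose()].
#' @param sample_rate Sampling rate in Hz.
#' @param n_freq_bins Number of frequency rows (>= 2) spanning
#'   \[0, `sample_rate` / 2\].
#' @return An object of class `hilbert_spectrum`: list with `time` (s),
#'   `freq` (Hz, bin centres), `energy` (matrix bins x time).
#' @export
hilbert_spectrum <- function(modes, sample_rate, n_freq_bins = 128L) {
  if (!inherits(modes, "ewt_modes"))
    abort_ewt("`modes` must be an ewt_modes object", "invalid_parameter")
  if (!is_number(n_freq_bins) || n_freq_bins < 2)
    abort_ewt("`n_freq_bins` must be >= 2", "invalid_parameter")
  n_freq_bins <- as.integer(n_freq_bins)
  m <- modes$modes
  nt <- nrow(m)
  f_edges <- seq(0, sample_rate / 2, length.out = n_freq_bins + 1L)
  energy <- matrix(0, nrow = n_freq_bins, ncol = nt)
  for (k in seq_len(ncol(m))) {
    if (all(m[, k] == 0)) next
    tr <- instantaneous_frequency(m[, k], sample_rate, source_mode = k)
    bin <- findInterval(tr$freq, f_edges, rightmost.closed = TRUE)
    bin <- pmin(pmax(bin, 1L), n_freq_bins)
    for (i in seq_len(nt))
      energy[bin[i], i] <- energy[bin[i], i] + tr$amp[i]^2
  }
  structure(list(time = (seq_len(nt) - 1) / sample_rate,
                 freq = (f_edges[-1] + f_edges[-length(f_edges)]) / 2,
                 energy = energy),
            class = "hilbert_spectrum")
}

#' @export
print.hilbert_spectrum <- function(x, ...) {
  cat(sprintf("<hilbert_spectrum> %d freq bins x %d time points, total energy %.4g\n",
              nrow(x$energy), ncol(x$energy), sum(x$energy)))
  invisible(x)
}
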