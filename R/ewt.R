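# Empirical wavelet transform: adaptive segmentation of the Fourier spectrum
# into N bands, a Meyer-type filter bank on those bands, mode extraction and
# exact reconstruction.  All filters are built on the signal's own FFT grid
# with Hermitian symmetry so modes are real.

#' Meyer auxiliary polynomial
#'
#' The standard transition polynomial
#' \eqn{\beta(x) = x^4 (35 - 84x + 70x^2 - 20x^3)}, monotone on \[0, 1\]
#' with \eqn{\beta(0)=0}, \eqn{\beta(1)=1} and
#' \eqn{\beta(x) + \beta(1-x) = 1}.  Used inside the cosine/sine filter
#' transitions; the complementarity identity is what makes the squared
#' filter responses sum to one.  Inputs outside \[0, 1\] are clamped.
#'
#' @param x Numeric vector.
#' @return \eqn{\beta(x)}, same length as `x`.
#' @export
meyer_beta <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

# Magnitude spectrum on [0, pi] with optional moving-average smoothing and
# detected local maxima (DC and Nyquist excluded as candidates).  Shared by
# ewt_segment() and ewt_select_n().
spectrum_maxima <- function(x, smooth_width = 3L, min_separation = 2L) {
  n <- length(x)
  if (n < 16L)
    abort_ewt("signal must have at least 16 samples", "invalid_parameter")
  half <- floor(n / 2)
  mag <- Mod(stats::fft(x))[seq_len(half + 1L)]     # bins 0..half (0-based)
  if (smooth_width > 1L) {
    k <- rep(1 / smooth_width, smooth_width)
    sm <- stats::filter(mag, k, sides = 2)
    sm[is.na(sm)] <- mag[is.na(sm)]
    mag_s <- as.numeric(sm)
  } else mag_s <- mag
  cand <- local_maxima(mag_s)                       # 1-based indices into mag_s
  cand <- cand[cand > 1L & cand < half + 1L]        # drop DC / Nyquist
  cand <- cand[mag_s[cand] > 1e-10 * max(mag_s)]    # FFT round-off is not a peak
  # merge maxima closer than min_separation bins, keeping the larger
  # (ties keep the lower frequency)
  if (length(cand) > 1L && min_separation > 0L) {
    cand <- cand[order(-mag_s[cand], cand)]
    keep <- logical(0)
    kept <- integer(0)
    for (i in cand) {
      if (!length(kept) || all(abs(kept - i) >= min_separation)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  list(mag = mag, mag_smooth = mag_s, maxima = cand, half = half, n = n)
}

#' Adaptive segmentation of the Fourier spectrum
#'
#' Splits the normalised frequency axis \[0, \eqn{\pi}\] into `n_segments`
#' contiguous bands adapted to the signal: the `n_segments` largest local
#' maxima of the magnitude spectrum are located, and each band boundary is
#' placed at the arithmetic midpoint between two consecutive selected
#' maxima.  With boundaries \eqn{0 = \omega_0 < \omega_1 < \dots <
#' \omega_N = \pi}, the bands \eqn{[\omega_{n-1}, \omega_n]} cover
#' \[0, \eqn{\pi}\] exactly.
#'
#' Maxima are detected on the magnitude spectrum after a light moving
#'-average smoothing (suppresses noise-spawned maxima); near-duplicate
#' maxima closer than `min_separation` bins are merged keeping the larger.
#' Equal-magnitude ties are resolved toward the lower frequency.
#'
#' @param x Real signal, length >= 16.
#' @param n_segments Number of bands N (>= 2), or `"auto"` to call
#'   [ewt_select_n()] with its defaults.
#' @param min_separation Minimum distance in FFT bins between distinct
#'   maxima (default 2).
#' @param smooth_width Moving-average width in bins applied to the
#'   magnitude spectrum before peak picking (default 3; 1 disables).
#' @param sample_rate Optional sampling rate in Hz, stored for unit
#'   conversion of the boundaries.
#'
#' @return An object of class `ewt_segmentation`: list with `boundaries`
#'   (normalised angular frequencies in (0, pi)), `n_segments`,
#'   `maxima_freqs`, `n_fft`, `sample_rate`.
#' @examples
#' k <- 0:511
#' x <- cos(0.2 * pi * k) + cos(0.6 * pi * k)
#' ewt_segment(x, n_segments = 2)
#' @export
ewt_segment <- function(x, n_segments = "auto", min_separation = 2L,
                        smooth_width = 3L, sample_rate = NULL) {
  sp <- spectrum_maxima(x, smooth_width = smooth_width,
                        min_separation = min_separation)
  if (max(sp$mag[-1]) <= 1e-12 * max(sp$mag[1], .Machine$double.eps))
    abort_ewt("signal spectrum is degenerate (constant signal)", "degenerate_spectrum")
  if (identical(n_segments, "auto"))
    n_segments <- ewt_select_n(x, smooth_width = smooth_width,
                               min_separation = min_separation)
  if (!is_number(n_segments) || n_segments < 2)
    abort_ewt("`n_segments` must be >= 2 or \"auto\"", "invalid_parameter")
  N <- as.integer(n_segments)
  cand <- sp$maxima
  if (length(cand) < N)
    abort_ewt(sprintf("requested %d segments but only %d local spectral maxima found",
                      N, length(cand)), "segmentation_error")
  # N largest maxima; ties at the cutoff keep the lower frequency
  sel <- cand[order(-sp$mag_smooth[cand], cand)][seq_len(N)]
  sel <- sort(sel)
  w <- 2 * pi * (sel - 1L) / sp$n                   # normalised angular freq
  bounds <- (w[-1] + w[-length(w)]) / 2
  structure(list(boundaries = bounds, n_segments = N, maxima_freqs = w,
                 n_fft = sp$n, sample_rate = sample_rate),
            class = "ewt_segmentation")
}

#' @export
print.ewt_segmentation <- function(x, ...) {
  cat(sprintf("<ewt_segmentation> N = %d, boundaries/pi = %s\n", x$n_segments,
              paste(sprintf("%.4f", x$boundaries / pi), collapse = ", ")))
  invisible(x)
}

#' Data-driven choice of the number of spectral segments
#'
#' Counts the local maxima of the (smoothed) magnitude spectrum whose height
#' exceeds `drop_ratio` times the global spectral maximum, and clamps the
#' count to \[2, `max_n`\].  This threshold rule is this package's stand-in
#' for an adaptive segment-number selection: prominent spectral peaks each
#' get a band, minor ones are absorbed.  The result can always be overridden
#' by passing an explicit `n_segments` to [ewt_segment()].
#'
#' @inheritParams ewt_segment
#' @param max_n Upper clamp for N (default 8).
#' @param drop_ratio Fraction of the global spectral maximum a local
#'   maximum must exceed to count (default 0.2).
#' @return Integer N in \[2, `max_n`\].  If no maximum clears the
#'   threshold, returns 2 with a warning.
#' @export
ewt_select_n <- function(x, max_n = 8L, drop_ratio = 0.2,
                         min_separation = 2L, smooth_width = 3L) {
  if (!is_number(max_n) || max_n < 2)
    abort_ewt("`max_n` must be >= 2", "invalid_parameter")
  check_number(drop_ratio, "drop_ratio", lower = 0, upper = 1)
  sp <- spectrum_maxima(x, smooth_width = smooth_width,
                        min_separation = min_separation)
  heights <- sp$mag_smooth[sp$maxima]
  n_above <- sum(heights > drop_ratio * max(sp$mag_smooth))
  if (n_above == 0L) {
    warn_ewt("no spectral maxima above threshold; falling back to N = 2",
             "degenerate_selection")
    return(2L)
  }
  as.integer(min(max(n_above, 2L), max_n))
}

#' Empirical wavelet filter bank
#'
#' Builds, on the FFT grid of the segmented signal, one low-pass scaling
#' filter for the first band and one band-pass empirical wavelet per
#' remaining band.  Each filter is flat (response 1) inside its band and
#' rolls off across a transition zone of half-width \eqn{\lambda_n = \gamma
#' \omega_n} centred on each boundary \eqn{\omega_n}, using the Meyer
#' cosine/sine transitions built on [meyer_beta()].  Because the sine rise
#' of one filter and the cosine fall of its neighbour are complementary,
#' the squared responses sum to exactly one at every frequency
#' (tight-frame / partition-of-unity property).
#'
#' @param seg An [ewt_segment()] result.
#' @param gamma Transition-width ratio in (0, 1).  Must be small enough
#'   that adjacent transition zones do not overlap:
#'   \eqn{\gamma < \min_n (\omega_{n+1}-\omega_n)/(\omega_{n+1}+\omega_n)}
#'   and \eqn{(1+\gamma)\omega_{N-1} \le \pi}.  The default `NULL` takes
#'   0.9 times the largest admissible value.
#' @param n_fft FFT length; defaults to the length recorded in `seg`.
#'
#' @return An object of class `ewt_filter_bank`: list with `responses`
#'   (matrix `n_fft` x N of real frequency responses, Hermitian-symmetric),
#'   `seg`, `gamma`, `lambda` (transition half-widths per boundary).
#' @export
ewt_filter_bank <- function(seg, gamma = NULL, n_fft = NULL) {
  if (!inherits(seg, "ewt_segmentation"))
    abort_ewt("`seg` must be an ewt_segmentation", "invalid_parameter")
  if (is.null(n_fft)) n_fft <- seg$n_fft
  b <- seg$boundaries
  N <- seg$n_segments
  bfull <- c(b, pi)                       # include the top band edge omega_N = pi
  gaps <- diff(bfull) / (bfull[-1] + bfull[-length(bfull)])
  gamma_max <- min(c(1, gaps))
  if (is.null(gamma)) gamma <- 0.9 * gamma_max
  check_number(gamma, "gamma", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (gamma >= gamma_max) {
    i <- which(gaps <= gamma)[1]
    abort_ewt(sprintf(
      "gamma = %.4f makes transition zones overlap between boundaries %.4f*pi and %.4f*pi (need gamma < %.4f)",
      gamma, bfull[i] / pi, bfull[i + 1] / pi, gamma_max), "invalid_gamma")
  }

  j <- 0:(n_fft - 1L)
  w_raw <- 2 * pi * j / n_fft
  w <- pmin(w_raw, 2 * pi - w_raw)        # Hermitian-symmetric |omega| in [0, pi]
  lam <- gamma * b

  resp <- matrix(0, nrow = n_fft, ncol = N)
  # transition helpers: rise (sin) entering a band, fall (cos) leaving it
  fall <- function(w, wb, l) cos(pi / 2 * meyer_beta((w - (wb - l)) / (2 * l)))
  rise <- function(w, wb, l) sin(pi / 2 * meyer_beta((w - (wb - l)) / (2 * l)))

  for (n in seq_len(N)) {
    lo <- if (n == 1L) NULL else b[n - 1L]
    hi <- if (n == N) NULL else b[n]
    r <- rep(1, n_fft)
    if (!is.null(lo)) {
      l <- gamma * lo
      r <- ifelse(w < lo - l, 0, ifelse(w <= lo + l, rise(w, lo, l), r))
    }
    if (!is.null(hi)) {
      l <- gamma * hi
      r <- ifelse(w > hi + l, 0, ifelse(w >= hi - l, pmin(r, fall(w, hi, l)), r))
    }
    resp[, n] <- r
  }
  structure(list(responses = resp, seg = seg, gamma = gamma, lambda = lam),
            class = "ewt_filter_bank")
}

#' @export
print.ewt_filter_bank <- function(x, ...) {
  cat(sprintf("<ewt_filter_bank> %d filters on an FFT grid of %d, gamma = %.4f\n",
              ncol(x$responses), nrow(x$responses), x$gamma))
  invisible(x)
}

#' Decompose a signal into empirical modes
#'
#' Splits the signal into one real mode per band of the filter bank.  Each
#' mode is the band's contribution to the tight-frame reconstruction: the
#' signal spectrum is multiplied by the band's squared frequency response
#' (analysis with the empirical wavelet followed by synthesis with the same
#' wavelet) and inverse-transformed.  Because the squared responses sum to
#' one, the modes sum back to the original signal exactly.
#'
#' @param x Real signal whose length matches the bank's FFT grid.
#' @param bank An [ewt_filter_bank()].
#' @return An object of class `ewt_modes`: list with `modes` (matrix
#'   `length(x)` x N, one column per band, low to high frequency), `bank`.
#' @examples
#' k <- 0:511
#' x <- cos(0.2 * pi * k) + cos(0.6 * pi * k)
#' m <- ewt_decompose(x, ewt_filter_bank(ewt_segment(x, 2)))
#' @export
ewt_decompose <- function(x, bank) {
  if (!inherits(bank, "ewt_filter_bank"))
    abort_ewt("`bank` must be an ewt_filter_bank", "invalid_parameter")
  if (length(x) != nrow(bank$responses))
    abort_ewt(sprintf("signal length %d does not match the bank's FFT grid %d",
                      length(x), nrow(bank$responses)), "contract_error")
  X <- stats::fft(x)
  N <- ncol(bank$responses)
  modes <- matrix(0, nrow = length(x), ncol = N)
  for (n in seq_len(N))
    modes[, n] <- Re(stats::fft(X * bank$responses[, n]^2, inverse = TRUE)) / length(x)
  structure(list(modes = modes, bank = bank), class = "ewt_modes")
}

#' @export
print.ewt_modes <- function(x, ...) {
  cat(sprintf("<ewt_modes> %d modes of length %d\n", ncol(x$modes), nrow(x$modes)))
  invisible(x)
}

#' Reconstruct a signal from its empirical modes
#'
#' The inverse of [ewt_decompose()]: the sum of all modes.  For modes
#' produced with a valid filter bank this reproduces the original signal to
#' floating-point accuracy (partition-of-unity of the squared responses).
#'
#' @param modes An `ewt_modes` object, or a numeric matrix with one mode
#'   per column.
#' @return Numeric vector, the reconstructed signal.
#' @export
ewt_reconstruct <- function(modes) {
  m <- if (inherits(modes, "ewt_modes")) modes$modes else modes
  if (!is.matrix(m)) m <- as.matrix(m)
  if (ncol(m) < 1L) abort_ewt("empty mode set", "contract_error")
  rowSums(m)
}

#' One-call empirical wavelet transform
#'
#' Convenience wrapper running [ewt_segment()], [ewt_filter_bank()] and
#' [ewt_decompose()] in sequence.
#'
#' @inheritParams ewt_segment
#' @inheritParams ewt_filter_bank
#' @return An `ewt_modes` object (the segmentation and bank are reachable
#'   through `$bank`).
#' @export
ewt <- function(x, n_segments = "auto", gamma = NULL, min_separation = 2L,
                smooth_width = 3L, sample_rate = NULL) {
  seg <- ewt_segment(x, n_segments = n_segments, min_separation = min_separation,
                     smooth_width = smooth_width, sample_rate = sample_rate)
  ewt_decompose(x, ewt_filter_bank(seg, gamma = gamma))
}
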