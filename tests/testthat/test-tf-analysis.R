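# Hilbert analysis: analytic signal, instantaneous frequency, frequency
# principal component, frequency-law fitting, Hilbert spectrum.

test_that("analytic signal recovers a tone's amplitude and phase slope", {
  fs <- 2000
  t <- seq(0, 1, by = 1 / fs)
  a <- analytic_signal(3 * cos(2 * pi * 100 * t), fs)
  interior <- 100:1900
  expect_true(all(abs(a$amp[interior] - 3) / 3 < 0.01))
  slope <- median(diff(a$phase[interior])) * fs
  expect_equal(slope, 2 * pi * 100, tolerance = 0.01)
  z <- analytic_signal(numeric(64), fs)
  expect_true(all(z$amp == 0) && all(z$phase == 0))
})

test_that("analytic amplitude tracks an AM envelope", {
  fs <- 4000
  t <- seq(0, 1, by = 1 / fs)
  env <- 1 + 0.5 * cos(2 * pi * 3 * t)
  a <- analytic_signal(env * cos(2 * pi * 400 * t), fs)
  interior <- 200:3800
  expect_lt(max(abs(a$amp[interior] - env[interior]) / env[interior]), 0.02)
})

test_that("instantaneous frequency is exact for tones and chirps", {
  fs <- 2000
  t <- seq(0, 1, by = 1 / fs)
  tr <- instantaneous_frequency(cos(2 * pi * 100 * t), fs)
  expect_true(median(tr$freq) > 99.5 && median(tr$freq) < 100.5)
  # linear chirp 100 -> 400 Hz: f(t) = 100 + 300 t, so 250 Hz at t = 0.5
  chirp <- cos(2 * pi * (100 * t + 150 * t^2))
  trc <- instantaneous_frequency(chirp, fs)
  f_mid <- trc$freq[which.min(abs(trc$time - 0.5))]
  expect_lt(abs(f_mid - 250) / 250, 0.02)
})

test_that("chirp IF error concentrates at the record ends", {
  fs <- 2000
  t <- seq(0, 1, by = 1 / fs)
  truth <- 100 + 300 * t
  trc <- instantaneous_frequency(cos(2 * pi * (100 * t + 150 * t^2)), fs)
  err <- abs(trc$freq - truth)
  n <- length(err)
  edge <- c(1:20, (n - 19):n)
  interior <- 101:(n - 100)
  expect_lt(max(err[interior]), max(err[edge]))
})

test_that("EWT modes of a two-tone signal have near-constant IF tracks", {
  fs <- 1000
  x <- tone_signal(c(0.2, 0.6), n = 1000)
  modes <- ewt(x, n_segments = 2)
  interior <- 100:900
  for (k in 1:2) {
    tr <- instantaneous_frequency(modes$modes[, k], fs)
    f <- tr$freq[interior]
    expect_lt(sd(f) / mean(f), 0.02)
    expect_equal(mean(f), c(0.1, 0.3)[k] * fs, tolerance = 0.01 * fs * c(0.1, 0.3)[k])
  }
})

test_that("principal component selects the dominant-amplitude track", {
  t <- seq(0, 1, by = 0.01)
  n <- length(t)
  tr1 <- track_from_freq(t, rep(100, n), amp = ifelse(t < 0.5, 2, 1))
  tr2 <- track_from_freq(t, rep(300, n), amp = ifelse(t < 0.5, 1, 2))
  pc <- principal_component(list(tr1, tr2))
  expect_true(all(pc$freq[t < 0.5] == 100))
  expect_true(all(pc$freq[t > 0.5] == 300))
  # single track is returned unchanged
  one <- principal_component(list(tr1))
  expect_equal(one$freq, tr1$freq)
  # all-zero amplitudes tie-break to the first mode
  z1 <- track_from_freq(t, rep(100, n), amp = rep(0, n))
  z2 <- track_from_freq(t, rep(300, n), amp = rep(0, n))
  expect_true(all(principal_component(list(z1, z2))$freq == 100))
})

test_that("principal component rejects mismatched grids and empty lists", {
  t <- seq(0, 1, by = 0.01)
  tr1 <- track_from_freq(t, rep(100, length(t)))
  tr2 <- track_from_freq(t[-1], rep(300, length(t) - 1))
  expect_error(principal_component(list()), class = "contract_error")
  expect_error(principal_component(list(tr1, tr2)), class = "contract_error")
})

test_that("a weak secondary mode barely disturbs the principal track", {
  fs <- 2000
  t <- seq(0, 1, by = 1 / fs)
  dom <- instantaneous_frequency(cos(2 * pi * 300 * t), fs)
  weak <- instantaneous_frequency(0.3 * cos(2 * pi * 700 * t), fs)
  pc <- principal_component(list(dom, weak))
  expect_lt(abs(median(pc$freq) - median(dom$freq)) / median(dom$freq), 0.01)
})

test_that("frequency-law fitting is exact on noiseless polynomials", {
  t <- seq(0, 1, length.out = 200)
  lin <- fit_frequency_law(track_from_freq(t, 50 + 10 * t))
  expect_equal(lin$f0, 50, tolerance = 1e-9)
  expect_equal(lin$k, 10, tolerance = 1e-9)
  expect_equal(lin$kn, 0, tolerance = 1e-9)
  quad <- fit_frequency_law(track_from_freq(t, 50 + 10 * t + 30 * t^2))
  expect_equal(quad$kn, 10, tolerance = 1e-9)    # raw coefficient 30 = 3 kn
  expect_lt(quad$residual_rms, 1e-9)
})

test_that("least-squares slope estimates are unbiased under frequency noise", {
  t <- seq(0, 1, length.out = 1000)
  ks <- vapply(1:200, function(s) {
    set.seed(s)
    fit_frequency_law(track_from_freq(t, 50 + 10 * t + rnorm(1000)), order = 1L)$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - 10) / 10, 0.02)
})

test_that("degenerate fits are refused", {
  tr <- track_from_freq(seq(0, 1, length.out = 50), rnorm(50))
  tr$time <- rep(1, 50)
  expect_error(fit_frequency_law(tr), class = "fit_error")
  expect_error(fit_frequency_law(track_from_freq(c(0, 1), c(1, 2))),
               class = "invalid_parameter")
})

test_that("amplitude weighting down-weights unreliable samples", {
  t <- seq(0, 1, length.out = 500)
  freq <- 100 + 50 * t
  freq[1:50] <- 0                                 # corrupted low-amplitude segment
  amp <- c(rep(1e-6, 50), rep(1, 450))
  fit_w <- fit_frequency_law(track_from_freq(t, freq, amp), weight_by_amp = TRUE)
  fit_u <- fit_frequency_law(track_from_freq(t, freq, amp))
  expect_lt(abs(fit_w$k - 50), abs(fit_u$k - 50))
})

test_that("Hilbert spectrum concentrates tone energy and conserves totals", {
  fs <- 1000
  x <- tone_signal(c(0.2, 0.6), n = 1000)
  modes <- ewt(x, n_segments = 2)
  hs <- hilbert_spectrum(modes, fs, n_freq_bins = 50)
  # total energy equals the sum of squared instantaneous amplitudes
  total_amp2 <- sum(vapply(1:2, function(k)
    sum(instantaneous_frequency(modes$modes[, k], fs)$amp^2), numeric(1)))
  expect_equal(sum(hs$energy), total_amp2, tolerance = 1e-6)
  # two ridges at the tone frequencies (100 and 300 Hz)
  row_energy <- rowSums(hs$energy)
  ridges <- hs$freq[row_energy > 0.1 * max(row_energy)]
  expect_true(any(abs(ridges - 100) <= 10) && any(abs(ridges - 300) <= 10))
  expect_error(hilbert_spectrum(modes, fs, n_freq_bins = 1),
               class = "invalid_parameter")
})

test_that("quadratic chirp parameters are recovered through the signal pipeline", {
  fs <- 4000
  t <- seq(0, 1, by = 1 / fs)
  f0 <- 400; k <- 300; kn <- 100                  # F(t) = 400 + 300 t + 300 t^2
  phase <- 2 * pi * (f0 * t + k / 2 * t^2 + kn * t^3)
  tr <- instantaneous_frequency(cos(phase), fs)
  interior <- tr$time > 0.05 & tr$time < 0.95
  sub <- track_from_freq(tr$time[interior], tr$freq[interior], tr$amp[interior])
  fit <- fit_frequency_law(sub)
  expect_lt(abs(fit$f0 - f0) / f0, 0.05)
  expect_lt(abs(fit$k - k) / k, 0.05)
  expect_lt(abs(fit$kn - kn) / kn, 0.05)
})
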