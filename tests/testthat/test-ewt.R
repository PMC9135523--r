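# EWT core: segmentation, segment-count selection, filter bank,
# decomposition, reconstruction.

test_that("two-tone spectrum segments at the midpoint between maxima", {
  x <- tone_signal(c(0.2, 0.6))
  seg <- ewt_segment(x, n_segments = 2)
  bin <- 2 * pi / 640
  expect_equal(seg$maxima_freqs, c(0.2, 0.6) * pi, tolerance = bin)
  expect_equal(seg$boundaries, 0.4 * pi, tolerance = bin)
})

test_that("three equal tones give midpoint boundaries at 0.35 and 0.65 pi", {
  x <- tone_signal(c(0.2, 0.5, 0.8))
  seg <- ewt_segment(x, n_segments = 3)
  expect_equal(seg$boundaries, c(0.35, 0.65) * pi, tolerance = 2 * pi / 640)
})

test_that("a pure tone cannot be split in two", {
  x <- tone_signal(0.2)
  err <- tryCatch(ewt_segment(x, 2), segmentation_error = identity)
  expect_s3_class(err, "segmentation_error")
  expect_match(conditionMessage(err), "1 local")
})

test_that("constant signals have a degenerate spectrum", {
  expect_error(ewt_segment(rep(1, 64), 2), class = "degenerate_spectrum")
})

test_that("segmentation is invariant to circular time shift", {
  set.seed(9)
  x <- tone_signal(c(0.2, 0.5, 0.8), amps = c(1, 0.8, 0.6)) + rnorm(640, sd = 0.05)
  seg1 <- ewt_segment(x, 3)
  shifted <- c(x[101:640], x[1:100])
  seg2 <- ewt_segment(shifted, 3)
  expect_identical(seg1$boundaries, seg2$boundaries)
})

test_that("segment-count selection thresholds on peak height and clamps", {
  expect_equal(ewt_select_n(tone_signal(c(0.2, 0.6), amps = c(1, 0.9)),
                            drop_ratio = 0.5), 2L)
  expect_equal(ewt_select_n(tone_signal(c(0.2, 0.6), amps = c(1, 0.1)),
                            drop_ratio = 0.5), 2L)
  x5 <- tone_signal(c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(ewt_select_n(x5, max_n = 4, drop_ratio = 0.5), 4L)
  expect_warning(ewt_select_n(rep(1, 64)), class = "degenerate_selection")
})

test_that("meyer beta has the required endpoint and symmetry properties", {
  expect_equal(meyer_beta(0), 0)
  expect_equal(meyer_beta(1), 1)
  x <- seq(0, 1, by = 0.01)
  expect_equal(meyer_beta(x) + meyer_beta(1 - x), rep(1, length(x)),
               tolerance = 1e-12)
})

test_that("squared filter responses partition unity for random segmentations", {
  set.seed(21)
  for (i in 1:20) {
    N <- sample(2:6, 1)
    b <- sort(runif(N - 1, 0.05 * pi, 0.95 * pi))
    while (min(diff(c(0, b, pi))) < 0.03 * pi) {
      b <- sort(runif(N - 1, 0.05 * pi, 0.95 * pi))
    }
    seg <- structure(list(boundaries = b, n_segments = N, maxima_freqs = NULL,
                          n_fft = 1024L, sample_rate = NULL),
                     class = "ewt_segmentation")
    bank <- ewt_filter_bank(seg)
    expect_lt(max(abs(rowSums(bank$responses^2) - 1)), 1e-10)
  }
})

test_that("low-pass response is flat below and zero above its transition", {
  seg <- structure(list(boundaries = 0.4 * pi, n_segments = 2L,
                        maxima_freqs = NULL, n_fft = 1000L, sample_rate = NULL),
                   class = "ewt_segmentation")
  bank <- ewt_filter_bank(seg, gamma = 0.1)        # lambda = 0.04 pi
  w <- 2 * pi * (0:499) / 1000
  lp <- bank$responses[1:500, 1]
  expect_true(all(lp[w <= 0.36 * pi - 1e-12] == 1))
  expect_true(all(lp[w >= 0.44 * pi + 1e-12] == 0))
})

test_that("overlapping transition zones are refused with the pair named", {
  seg <- structure(list(boundaries = c(0.3, 0.35) * pi, n_segments = 3L,
                        maxima_freqs = NULL, n_fft = 512L, sample_rate = NULL),
                   class = "ewt_segmentation")
  err <- tryCatch(ewt_filter_bank(seg, gamma = 0.3), invalid_gamma = identity)
  expect_s3_class(err, "invalid_gamma")
  expect_match(conditionMessage(err), "0.30.*pi.*0.35.*pi")
})

test_that("two-tone decomposition separates the tones with <1% cross-talk", {
  x <- tone_signal(c(0.2, 0.6))
  modes <- ewt(x, n_segments = 2)
  t1 <- tone_signal(0.2); t2 <- tone_signal(0.6)
  expect_lt(mean((modes$modes[, 1] - t1)^2) / mean(t1^2), 0.01)
  expect_lt(mean((modes$modes[, 2] - t2)^2) / mean(t2^2), 0.01)
  # energy of each tone lands almost entirely in its own mode
  m1 <- ewt_decompose(t1, modes$bank)
  expect_gt(sum(m1$modes[, 1]^2) / sum(t1^2), 0.99)
  expect_lt(sum(m1$modes[, 2]^2) / sum(t1^2), 0.01)
})

test_that("a zero signal decomposes to all-zero modes", {
  x <- tone_signal(c(0.2, 0.6))
  bank <- ewt_filter_bank(ewt_segment(x, 2))
  z <- ewt_decompose(numeric(640), bank)
  expect_true(all(z$modes == 0))
})

test_that("decompose-reconstruct is exact for arbitrary signals", {
  set.seed(3)
  x <- rnorm(1024)
  modes <- ewt(x, n_segments = 4)
  expect_lt(max(abs(ewt_reconstruct(modes) - x)), 1e-8 * max(abs(x)))
  # single mode reconstructs to itself
  expect_identical(ewt_reconstruct(matrix(x, ncol = 1)), x)
})

test_that("length mismatches between signal and bank are contract errors", {
  x <- tone_signal(c(0.2, 0.6))
  bank <- ewt_filter_bank(ewt_segment(x, 2))
  expect_error(ewt_decompose(x[1:100], bank), class = "contract_error")
})

test_that("in-band pure tones keep >=99% of their energy in one mode", {
  set.seed(14)
  for (i in 1:5) {
    freqs <- sort(sample(seq(0.1, 0.9, by = 0.05), 3))
    if (min(diff(freqs)) < 0.15) next
    x <- tone_signal(freqs, n = 1280)
    bank <- ewt_filter_bank(ewt_segment(x, 3))
    for (j in 1:3) {
      tj <- tone_signal(freqs[j], n = 1280)
      mj <- ewt_decompose(tj, bank)
      expect_gt(sum(mj$modes[, j]^2) / sum(tj^2), 0.99)
    }
  }
})
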