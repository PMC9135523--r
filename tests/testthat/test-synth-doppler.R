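# Simulator module: waveforms, flow profile, Doppler forward model,
# attenuation, cohorts.

test_that("umbilical waveform hits VS and VD and is periodic", {
  wf <- umbilical_waveform(vs = 0.6, vd = 0.2, heart_rate = 120, duration = 2,
                           sample_rate = 2000)
  expect_equal(max(wf$velocity), 0.6, tolerance = 0.01)
  expect_equal(min(wf$velocity), 0.2, tolerance = 0.01)
  # periodic with period 60/120 = 0.5 s: compare one full period to the next
  period_n <- 1000
  expect_equal(wf$velocity[1:period_n], wf$velocity[period_n + (1:period_n)],
               tolerance = 1e-9)
  # about 4.83 cycles in 2 s at 145 bpm
  expect_equal(2 / (60 / 145), 4.833, tolerance = 1e-3)
})

test_that("pulseless waveform degenerates to a constant", {
  wf <- umbilical_waveform(vs = 0.5, vd = 0.5, heart_rate = 120, duration = 1)
  expect_true(all(wf$velocity == 0.5))
})

test_that("RI computed on the simulated waveform matches (vs-vd)/vs", {
  wf <- umbilical_waveform(vs = 0.6, vd = 0.2, heart_rate = 145, duration = 2)
  sdm <- extract_sd(wf, heart_rate_hint = 145)
  expect_equal(resistance_index(sdm$vs, sdm$vd), (0.6 - 0.2) / 0.6,
               tolerance = 0.01)
})

test_that("waveform parameter validation rejects bad input", {
  expect_error(umbilical_waveform(vs = 0.2, vd = 0.6), class = "invalid_parameter")
  expect_error(umbilical_waveform(vs = 0.6, vd = 0.2, heart_rate = 145,
                                  duration = 0.2), class = "invalid_parameter")
})

test_that("parabolic profile follows the Poiseuille law", {
  expect_equal(parabolic_profile(0.4, 0, 1), 0.4)
  expect_equal(parabolic_profile(0.4, 1, 1), 0)
  expect_equal(parabolic_profile(0.4, 1 / sqrt(2), 1), 0.2)
  expect_error(parabolic_profile(0.4, 2, 1), class = "invalid_parameter")
  expect_error(parabolic_profile(0.4, 0, -1), class = "invalid_parameter")
})

test_that("constant-flow simulation puts the spectral peak at the Doppler shift", {
  geom <- default_geometry()
  n <- 2^13
  wf <- velocity_waveform(seq(0, by = 1 / 5000, length.out = n + 1),
                          rep(0.3, n + 1))
  sig <- simulate_doppler(wf, geom, n_scatterers = 10, seed = 7)
  mag <- Mod(stats::fft(sig$samples[1:n]))[2:(n / 2)]
  f_peak <- which.max(mag) * 5000 / n
  f_expected <- 2 * 0.3 * cos(60 * pi / 180) * 3.5e6 / 1540   # ~681.8 Hz
  expect_lt(abs(f_peak - f_expected), 5000 / n + 1e-9)        # within one FFT bin
})

test_that("zero-velocity truth gives a DC-only signal (noise-free)", {
  geom <- default_geometry()
  wf <- velocity_waveform(seq(0, 1, by = 1 / 5000), rep(0, 5001))
  sig <- simulate_doppler(wf, geom, n_scatterers = 5, seed = 3)
  expect_lt(diff(range(sig$samples)), 1e-12)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  geom <- default_geometry(snr_db = 10)
  wf <- umbilical_waveform(0.6, 0.2, duration = 1)
  a <- simulate_doppler(wf, geom, seed = 11)
  b <- simulate_doppler(wf, geom, seed = 11)
  expect_identical(a$samples, b$samples)
})

test_that("aliasing is refused with the offending frequency named", {
  geom <- suppressWarnings(beam_geometry(3.5e6, 0, 1540, sample_rate = 500))
  wf <- velocity_waveform(seq(0, 1, by = 1 / 500), rep(0.5, 501))
  err <- tryCatch(simulate_doppler(wf, geom), aliasing_error = identity)
  expect_s3_class(err, "aliasing_error")
  expect_match(conditionMessage(err), "[0-9.]+ Hz")
})

test_that("forward model matches the Doppler equation by zero-crossing count", {
  geom <- default_geometry()
  dur <- 2
  wf <- velocity_waveform(seq(0, dur, by = 1 / 5000), rep(0.4, 5000 * dur + 1))
  sig <- simulate_doppler(wf, geom, n_scatterers = 1, seed = 5)
  crossings <- sum(diff(sign(sig$samples)) != 0)
  f_zc <- crossings / (2 * dur)
  f_true <- velocity_to_doppler(0.4, geom)
  expect_lt(abs(f_zc - f_true) / f_true, 0.01)
})

test_that("attenuation follows the exponential law", {
  geom <- default_geometry()
  wf <- umbilical_waveform(0.6, 0.2, duration = 1)
  sig <- simulate_doppler(wf, geom, seed = 1)
  expect_identical(apply_attenuation(sig, 0, 0.1)$samples, sig$samples)
  a <- log(2) / (geom$carrier_freq * 0.05)
  half <- apply_attenuation(sig, a, 0.05)
  expect_equal(half$samples, sig$samples / 2, tolerance = 1e-12)
  doubled <- apply_attenuation(sig, a, 0.10)
  expect_equal(doubled$attenuation_factor, half$attenuation_factor^2,
               tolerance = 1e-12)
  expect_error(apply_attenuation(sig, -1, 0.1), class = "invalid_parameter")
})

test_that("default cohort has the study group sizes and exact index identities", {
  coh <- make_cohort(seed = 1)
  expect_equal(nrow(coh), 142)
  expect_equal(sum(coh$group == "FGR"), 40)
  expect_equal(sum(coh$group == "control"), 102)
  expect_true(all(coh$vs > coh$vd), TRUE)
  expect_equal(coh$cross_section_area, pi * (coh$diameter / 2)^2, tolerance = 1e-12)
  expect_equal(coh$ri, (coh$vs - coh$vd) / coh$vs, tolerance = 1e-12)
  expect_equal(coh$pi, (coh$vs - coh$vd) / coh$v_mean, tolerance = 1e-12)
  expect_equal(coh$mean_flow, mean_flow(coh$v_mean, coh$diameter), tolerance = 1e-12)
  expect_identical(make_cohort(seed = 4)$vs, make_cohort(seed = 4)$vs)
})

test_that("zero-SD cohort collapses to group means with exact RI", {
  eff <- cohort_effects()
  for (g in c("control", "fgr")) {
    eff[[g]]$vs[2] <- 0; eff[[g]]$vd[2] <- 0
    eff[[g]]$diameter[2] <- 0; eff[[g]]$v_mean_noise_sd <- 0
  }
  coh <- make_cohort(4, 4, effect_config = eff, seed = 2)
  fgr <- coh[coh$group == "FGR", ]
  expect_equal(length(unique(fgr$vs)), 1L)
  expect_equal(fgr$ri, (fgr$vs - fgr$vd) / fgr$vs, tolerance = 1e-15)
})

test_that("identical group distributions give mostly non-significant VS tests", {
  hits <- vapply(1:100, function(s) {
    coh <- make_cohort(effect_config = cohort_effects(null = TRUE), seed = s)
    compare_cohort(coh, variables = "vs")$significant
  }, logical(1))
  expect_gte(mean(!hits), 0.90)
})

test_that("invalid cohort configurations are rejected", {
  eff <- cohort_effects()
  eff$fgr$vs <- c(5, 2)             # mean vs below mean vd
  expect_error(make_cohort(effect_config = eff), class = "invalid_parameter")
  eff2 <- cohort_effects()
  eff2$control$vd[2] <- -1
  expect_error(make_cohort(effect_config = eff2), class = "invalid_parameter")
  expect_error(make_cohort(n_fgr = 1), class = "invalid_parameter")
})
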