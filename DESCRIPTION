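Package: ewtflow
Title: Empirical Wavelet Transform Analysis of Doppler Blood-Flow Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Time-frequency analysis of pulsed-wave Doppler ultrasound
    blood-flow signals with the empirical wavelet transform (EWT):
    adaptive Fourier-spectrum segmentation, Meyer-type empirical wavelet
    filter banks with perfect reconstruction, Hilbert instantaneous
    amplitude/frequency tracks, frequency principal-component extraction
    and polynomial frequency-law fitting.  Converts Doppler shifts to
    blood velocity, benchmarks EWT velocity estimation against a
    short-time Fourier transform baseline by normalised root-mean-square
    error, and computes umbilical-artery hemodynamic indices (RI, PI,
    S/D, mean volume flow) with two-group comparison statistics.  A
    built-in simulator generates pulsatile umbilical velocity waveforms,
    Doppler echo signals with known ground truth, and synthetic
    fetal-growth-restriction/control cohorts so the full pipeline runs
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
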