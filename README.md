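# ewtflow

Adaptive time–frequency analysis of pulsed-wave Doppler ultrasound
blood-flow signals with the **empirical wavelet transform (EWT)**, plus the
umbilical-artery hemodynamic indices used to screen for fetal growth
restriction (FGR).

## The problem and who this is for

Pulsed-wave Doppler turns the motion of blood into a frequency shift: a
scatterer moving at velocity $v$ past a transducer emitting at carrier
frequency $f_0$ returns an echo shifted by

$$f_d = \frac{2\,v\,\cos\alpha\, f_0}{c},$$

with $\alpha$ the insonation angle and $c \approx 1540$ m/s the speed of
sound in tissue.  Estimating the velocity waveform from the demodulated
Doppler signal is a non-stationary spectral-estimation problem: the shift
sweeps through the spectrum once per cardiac cycle, and windowed methods
(the classic spectrogram) trade time against frequency resolution.

The EWT sidesteps the fixed-window compromise.  It segments the signal's
Fourier spectrum $[0,\pi]$ adaptively at the midpoints between its $N$
largest local maxima, builds a Meyer-type tight-frame filter bank on those
segments (flat passbands, cosine/sine transitions of half-width
$\lambda_n=\gamma\omega_n$ over the polynomial
$\beta(x)=x^4(35-84x+70x^2-20x^3)$), and extracts one "single-component"
mode per band.  Each mode's Hilbert analytic signal gives an instantaneous
amplitude $a_i(t)$ and frequency $F_i(t)$; the **frequency principal
component**

$$K(t) = F_{\arg\max_j a_j(t)}(t)$$

follows whichever band is physically active and is little disturbed by
noise, which spreads over all bands.  $K(t)$ converts to velocity through
the Doppler equation, and accuracy is scored by the normalised
root-mean-square error

$$\mathrm{NRMSE}=\sqrt{\frac{\sum_c\,(v(c)-\bar v(c))^2}{\sum_c \bar v(c)^2}}$$

against ground truth, with a Hann-window STFT peak tracker as the baseline.
On top of the velocity waveform the package computes the standard clinical
indices — $RI=(S-D)/S$, $PI=(S-D)/V_{mean}$, $S/D$, and mean volume flow
$Q=V_{mean}\,\pi(d/2)^2$ — and compares them between groups with
independent-sample t-tests.

The package is aimed at biomedical signal-processing work: no clinical
recordings are required, because a built-in simulator generates pulsatile
umbilical waveforms, Doppler echo signals with known ground truth, and
synthetic FGR/control cohorts.

## Worked example

```r
library(ewtflow)

geom  <- beam_geometry(carrier_freq = 3.5e6, angle_deg = 55,
                       sample_rate = 5000, snr_db = 20)
truth <- umbilical_waveform(vs = 0.6, vd = 0.2, heart_rate = 145, duration = 2)
sig   <- simulate_doppler(truth, geom, n_scatterers = 20, seed = 42)
sig
#> <doppler_signal> 10001 samples @ 5000 Hz (2 s), with geometry, with ground truth

est <- estimate_velocity_ewt(sig)
est
#> <velocity_estimate> method ewt, 200 points, v in [0.1929, 0.6021] m/s, NRMSE vs truth 0.005514
```

The estimate tracks the simulated waveform (peak systolic 0.6, end
diastolic 0.2 m/s) with an NRMSE of 0.0055; the same recording through the
STFT baseline (`estimate_velocity_stft(sig)`) scores 0.029.  Clinical
indices from the estimated waveform:

```r
str(index_set(est$waveform, heart_rate_hint = 145, diameter = 3.8))
#> $ vs       : num 60.1      # cm/s
#> $ vd       : num 20
#> $ v_mean   : num 34.1
#> $ ri       : num 0.667     # (60.1 - 20) / 60.1
#> $ pi       : num 1.18
#> $ sd_ratio : num 3.01
#> $ mean_flow: num 232       # mL/min through a 3.8 mm vessel
```

A synthetic cohort with the default group effects reproduces the expected
screening pattern — systolic/diastolic velocities and vessel calibre lower
and pulsatility higher in FGR, mean velocity and volume flow statistically
flat:

```r
coh <- make_cohort(seed = 1)          # 40 FGR / 102 control subjects
compare_cohort(coh, variables = c("vs", "vd", "pi", "diameter",
                                  "v_mean", "mean_flow"))
#>    variable statistic  p_value significant
#> 1        vs     -4.53 1.26e-05        TRUE
#> 2        vd    -18.47 2.32e-39        TRUE
#> 3        pi      2.23 2.76e-02        TRUE
#> 4  diameter     -5.07 1.27e-06        TRUE
#> 5    v_mean      1.56 1.22e-01       FALSE
#> 6 mean_flow     -0.20 8.43e-01       FALSE
```

A thin command-line front end wraps the same functions
(`inst/cli/ewtflow.R`, subcommands `simulate`, `decompose`, `analyze`,
`estimate`, `indices`, `compare`, `evaluate`, `benchmark`).

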