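---
title: "Methods: empirical wavelet analysis of Doppler blood-flow signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical wavelet analysis of Doppler blood-flow signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ewtflow)
```

This vignette is the package's own account of its methods: the signal
model, the empirical wavelet construction and the conventions chosen where
several are defensible, the simulator that stands in for clinical
recordings, and the statistical design of the synthetic cohorts.

## Signal model

We work on the demodulated, audio-band Doppler-shift signal rather than on
radio-frequency echoes.  A scatterer moving at velocity $v(t)$ contributes
a sinusoid at the instantaneous Doppler frequency
$f_d(t) = 2 v(t) \cos(\alpha) f_0 / c$; the recorded signal is a sum of
such components over the scatterers in the sample volume plus additive
white Gaussian noise.  This is the quantity every stage of the method
operates on, and simulating it directly keeps sampling rates at a few kHz
instead of tens of MHz.  Amplitude attenuation along the propagation path
follows the frequency-proportional exponential law
$W_r = W_0 e^{-a f_0 r}$, exposed in `apply_attenuation()` with the
attenuation coefficient $a$ and depth $r$ as explicit parameters.

Assumptions worth stating: flow is laminar (a Poiseuille parabolic profile
across the vessel), the insonation angle is known and fixed over the
recording, and the sampling rate respects the Nyquist limit for the peak
Doppler shift — the simulator refuses aliasing configurations rather than
wrapping frequencies.

## The empirical wavelet transform

**Segmentation.**  The magnitude FFT on $[0, \pi]$ is lightly smoothed
(moving average, default width 3 bins) to suppress noise-spawned maxima;
local maxima closer than `min_separation` (default 2 bins) are merged
keeping the larger, and maxima below $10^{-10}$ of the global maximum are
discarded as FFT round-off.  The $N$ largest surviving maxima are selected
(ties toward the lower frequency) and each boundary is the arithmetic
midpoint of two consecutive maxima.  A spectral *median* between maxima
would be an alternative reading of "the median frequency between two
maxima"; the midpoint is implemented because it is the standard rule and
the two coincide for symmetric peaks.

**Choosing N.**  No published flowchart fixes the segment count, so
`ewt_select_n()` implements a documented stand-in: count the local maxima
above `drop_ratio` (default 0.2) times the global spectral maximum, clamp
to $[2, \texttt{max\_n}]$ (default max 8).  An explicit `n_segments`
always overrides it.

**Filter bank.**  Filters are flat inside their band with Meyer
cosine/sine transitions of half-width $\lambda_n = \gamma\,\omega_n$
around each boundary, built on
$\beta(x) = x^4(35 - 84x + 70x^2 - 20x^3)$.  Because
$\beta(x) + \beta(1-x) = 1$, the sine rise of one filter is the exact
complement of the neighbouring cosine fall and the squared responses sum
to one everywhere (tight frame).  The admissible transition ratio must
keep zones from overlapping,
$\gamma < \min_n (\omega_{n+1}-\omega_n)/(\omega_{n+1}+\omega_n)$ with the
top edge $\omega_N = \pi$ included in the minimum; the default takes 0.9
of that bound.

**Mode convention.**  A mode is defined as the band's contribution to the
tight-frame reconstruction: inverse FFT of the spectrum multiplied by the
*squared* response (analysis followed by synthesis with the same real,
Hermitian-symmetric filter).  Two properties follow exactly: modes are
real, and they sum to the original signal to machine precision.  For
content in a flat passband this coincides with the single-application
convention used by some implementations; the price is that for broadband
content the mode *energies* are not additive (the reconstruction is exact,
the energy bookkeeping is not), which we consider the right trade for an
estimation pipeline whose contract is exact invertibility.

## Hilbert analysis and the frequency law

Instantaneous frequency is the central difference of the unwrapped
analytic phase (one-sided at the endpoints) over $2\pi$.  No smoothing is
applied by default; phase differentiation is noisy exactly where the
amplitude is small, and the frequency principal component — at each
instant, take the frequency of the mode with the largest instantaneous
amplitude, ties toward the lower band — already ignores those samples.
Negative frequency samples (low-amplitude phase jitter) are clipped to
zero and counted in the track's `n_clipped`, never silently masked, so
grids stay uniform.

The Hilbert transform's edge effect is real and observable: on chirps the
instantaneous-frequency error at the record ends exceeds the interior
error (asserted as a test).  Consumers that care should trim a few tens of
samples per end, as `index_set()`'s per-cycle medians effectively do.

Frequency laws are fitted by (optionally amplitude-weighted) least squares
of $F(t) = F_0 + k t + 3 k_n t^2 + e(t)$.  The factor 3 on the quadratic
term is kept literally as a reporting convention: `kn` is one third of the
raw quadratic coefficient, so the printed symbols map one-to-one onto the
model.  The benchmark condition used in the tests and the acceptance
script — $F_0 = 50$ Hz, $k = 200$ Hz/s, $k_n = 100$ Hz/s², 2000 points
over 1 s, frequency noise at 20 dB SNR — was fixed a priori from the OLS
variance of the quadratic design on $[0,1]$
($\mathrm{Var}(\hat b) = \sigma^2\,\mathrm{diag}(9, 192, 180)/n$ to first
order), so that each coefficient's sampling error sits comfortably below
the 5 % acceptance band without being trivially small.

## Velocity estimation

The EWT pathway aggregates the principal-component track onto a uniform
grid (stride `window_s`, default 10 ms) by per-window medians and converts
through the Doppler equation; negative velocities are floored at zero.
A spectrum too simple to segment — a single clean peak, as for noise-free
constant flow — falls back to direct Hilbert demodulation of the whole
signal as one mode, preserving the estimator's contract on degenerate
inputs.

The STFT baseline is deliberately conventional: Hann window (default
10 ms), 50 % overlap, per-window spectral peak, with a 95th-percentile
spectral-power envelope rule as an option.  Window times are centred on
the window (the underlying spectrogram reports window starts).  All of
these are flags, because no single baseline configuration is canonical.

## What the simulator emulates — and what it does not

The umbilical waveform template is a raised-cosine systolic bump of
relative width `sys_frac` (default 0.7) rising from the end-diastolic
level VD to the systolic peak VS, flat diastole, at a default fetal heart
rate of 145 beats/min.  It reproduces the quantities the indices consume —
VS, VD, and a mean velocity of $VD + \tfrac{sys\_frac}{2}(VS - VD)$ — and
the spectral sweep a tracker must follow.  It does **not** claim
morphological realism: no dicrotic notch, no diastolic decay, no
beat-to-beat variability.  Scatterers are drawn uniformly over the vessel
cross-section (density proportional to radius) for the parabolic profile;
the benchmark's "different axial positions" are realised as radial
sample-volume placements, each scaling the centerline waveform by the
local Poiseuille factor.  Wall clutter, spectral broadening, and beam
geometry in 2-D/3-D are out of scope, so passing tests demonstrate
correct frequency tracking and index algebra under this idealised forward
model — not robustness to clutter or probe motion.

SNR is defined as signal power over noise power in dB; for an identically
zero truth waveform the noise floor is referenced to a unit-amplitude
tone's power (0.5) so the setting remains meaningful.

## Cohort design

The synthetic cohorts (default 40 FGR / 102 control) sample per-subject
primitives — VS, VD, vessel diameter, and a mean velocity linked to VS/VD
through a group-specific systolic fraction plus independent noise — and
derive every index column through the index functions, so the table
satisfies RI/PI/area/flow identities exactly.  The default effects were
fixed by an a-priori power analysis at those group sizes (two-sample
t-test, $SE \propto \sqrt{1/40 + 1/102}$): VS and VD deficits large enough
to be detected essentially always, a diameter deficit of about 0.7
within-group SDs (small in absolute terms against a deliberately tight
0.10 mm spread, so the calibre difference is detectable while its
knock-on effect on derived flow stays small), and the FGR mean-velocity
link raised just enough to split the area deficit's effect evenly between
mean velocity and flow, keeping both below the detectability threshold.

One consequence is worth flagging: with mean velocity flat and PI higher
in FGR, the systolic–diastolic excursion $S - D$ must be larger in FGR,
and with $S$ lower that forces $RI = (S-D)/S$ higher too.  A cohort whose
indices are internally consistent cannot simultaneously show PI up,
V_mean flat, VS/VD down *and* RI unchanged; the generator therefore
reproduces the tested direction pattern (VS, VD, PI, diameter, area
significant; mean velocity and flow not), and RI comes out significantly
higher in FGR as the algebra demands.

The independent-samples t-test defaults to the pooled-variance form, the
conventional choice for reported clinical tables; Welch's form is a flag
and is the better default for unequal spreads.  No multiple-testing
correction is applied by default (a Bonferroni option exists), matching
common practice in the application domain.

## Numerical choices and problem sizes

* FFT-grid filters are Hermitian-symmetric by construction, so modes are
  exactly real; reconstruction error on random signals is at the
  $10^{-15}$ level.
* Peak detection treats plateaus as single maxima (midpoint index) and
  ignores anything below $10^{-10}$ of the spectral maximum.
* Test tones are bin-aligned (integer periods on the FFT grid) wherever an
  assertion is about band algebra rather than leakage robustness.
* The test suite and acceptance script use desk-scale sizes chosen as the
  package's own benchmark conditions: 2-second recordings at 5 kHz,
  4096-point reconstruction checks, 50 seeds per SNR level for the
  estimator comparison, 100 seeded cohorts for the significance-rate
  checks, 20 seeds for the constant-flow round trip.

## Known limitations

* The waveform template and cohort distributions are synthetic stand-ins;
  nothing here validates the method on clinical recordings.
* The EWT segmentation assumes the spectral peaks of interest dominate
  the magnitude spectrum; strong clutter near DC would claim a band.
* Instantaneous-frequency tracks degrade near record ends (Hilbert edge
  effect) and at low instantaneous amplitude.
* The estimator returns non-negative velocities only; flow reversal would
  need directional (complex-baseband) demodulation, which is out of
  scope.
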