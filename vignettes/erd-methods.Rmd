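---
title: "Measuring mu and alpha event-related desynchronization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mu and alpha event-related desynchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The quantity being estimated

Sensorimotor mu and occipital alpha rhythms are 8--13 Hz oscillations whose
power drops when the underlying cortex engages -- during action observation
and emotion processing for mu, with visual attention for alpha. This package
quantifies that drop as an event-related desynchronization (ERD) index per
participant, stimulus character and emotion:

1. each 6000 ms trial contains a *static* phase (neutral still image; analysis
   window 800--1900 ms) and a *dynamic* phase (morphing expression; analysis
   window 1950--4000 ms);
2. band power spectral density (PSD) over 8--13 Hz is estimated in each window
   for a central electrode cluster (C3, C1, Cz, C2, C4; the mu signal) and an
   occipital cluster (O1, Oz, O2; the alpha signal);
3. the per-trial *ratio* dynamic PSD / static PSD is screened for outliers
   (3 scaled MADs from the per-participant, per-cluster median);
4. kept ratios are averaged per participant x character x emotion and
   log10-transformed (*mean-then-log*, in that order).

Negative values indicate ERD (power suppression), positive values ERS, zero no
change. The within-trial static baseline cancels between-participant power
differences from electrode impedance and anatomy, which is why the ratio -- not
raw band power -- is the analysis unit.

The inference layer regresses the index on condition dummies by OLS with
CR1 cluster-robust standard errors at the participant level (t reference with
G - 1 degrees of freedom), contrasts condition levels, tests the
static-vs-dynamic phase contrast by paired t, and complements p-values with
Jeffreys--Zellner--Siow (JZS) Bayes factors (Cauchy prior on the standardized
effect, scale sqrt(2)/2 by default).

## The synthetic-data generator

`sim_config()` + `build_schedule()` + `synthesize_recording()` emulate the
study design the pipeline targets: a 3 (emotion) x 3 (character group)
within-subject Go/No-Go paradigm, 8 characters (2 in-party, 2 out-party,
4 non-politician) x 3 emotions x 4 blocks = 96 trials, fixation jittered
uniformly in 2500--3000 ms, 6000 ms stimulus, then a 2000 ms + 3000 ms cue
period; 512 Hz on a 64-channel 10-20 montage.

Each recording is the sum of

* **1/f background noise** per channel (`noise_exponent = 1`,
  `noise_sd = 3` microvolts, synthesized spectrally);
* **two amplitude-modulated oscillators**: a mu source projected onto the
  scalp with Gaussian weights peaking at the central cluster, and an alpha
  source peaking occipitally (`leakage_width = 0.3` head-radius units). Their
  instantaneous frequencies drift slowly (Ornstein-Uhlenbeck, sd 0.5 Hz,
  1 s correlation time) around 11.6 Hz (mu) and 9.4 Hz (alpha), clipped to
  +/-1.5 drift sd;
* optional **blink-like transients** on the frontal channels (Poisson
  arrivals, raised-cosine pulses), disabled by default.

During each trial's dynamic window (2000--4000 ms after stimulus onset) the
oscillator amplitude is multiplied by the condition's attenuation factor `a`;
100 ms raised-cosine ramps sit *outside* that window (down-ramp 1900--2000 ms,
up-ramp 4000--4100 ms), so the full video window carries the attenuated
amplitude and neither analysis window overlaps a transition. Because power
scales as amplitude squared, the true log10 power ratio of a condition is
exactly `2 * log10(a)`; `synthesize_recording()` returns this ground truth per
participant, condition and cluster. The default attenuations --- out-party
0.70, in-party and non-politician 0.85 --- encode the qualitative pattern the
pipeline is designed to detect (strongest ERD for out-party stimuli) at
condition contrasts of about -0.17 log10 units.

Parameter meanings and rationale for the non-obvious defaults:

* `subject_sd = 0.08` (log10 units): between-participant lognormal jitter on
  the attenuation, independent per condition and cluster. Individual ERD
  magnitudes vary substantially in practice; without this component the
  Monte-Carlo spread of group estimates would be unrealistically tight.
* `osc_amplitude = c(mu = 10, alpha = 12)` microvolts against a 3 microvolt
  1/f background gives a band signal-to-noise ratio of roughly 40:1 at the
  cluster electrodes -- pronounced, clearly resolvable idling rhythms. The
  recovery analyses assume the noise floor contributes little to band power;
  see *Known limitations* for what happens as SNR drops.
* distinct centre frequencies (11.6 / 9.4 Hz): sensorimotor mu typically
  peaks somewhat higher than posterior alpha. Technically this keeps the two
  rhythms spectrally separable: their drift ranges never share an
  instantaneous frequency, and stay 0.65 Hz inside the 8/13 Hz band edges so
  that short-window spectral leakage stays inside the analysis band.

### What the generator does not emulate

No volume-conducted dipole physics (weights are schematic Gaussian kernels),
no eye-movement channels or EMG, no line noise, no non-stationary background
(drowsiness, impedance drift). Passing tests therefore demonstrate that the
*pipeline* recovers known ground truth under controlled conditions, not that
any particular real dataset is artifact-free.

## Preprocessing chain

`preprocess_recording()` runs: FFT resample to 250 Hz -> zero-phase band
filter (0.1--40 Hz) -> kurtosis-based bad-channel detection and
inverse-distance interpolation -> 6000 ms stimulus-locked epochs -> robust-z
epoch rejection -> ICA hook (no-op by default) -> average reference.

Numerical choices:

* **Filtering** applies the squared magnitude of an order-2 Butterworth
  high-pass and order-6 low-pass on the DFT grid. The squared magnitude is
  exactly the response of forward-backward (filtfilt) application, with
  identically zero phase, so the static/dynamic boundary is not smeared by
  group delay; the effective order-12 low-pass leaves less than 10% of a
  50 Hz component (> 20 dB down on the passband), removing line-noise
  harmonics. Boundary behaviour is circular; recordings carry quiet padding.
* **Bad channels**: per-channel excess kurtosis, robust-z-scored across
  channels (median / scaled MAD), flagging channels with z above 5. The test
  is one-sided deliberately: spiky artifact channels are strongly
  leptokurtic, whereas rhythm-dominated channels are platykurtic (a pure
  sinusoid has excess kurtosis -1.5) and are the *healthiest* channels in the
  montage. The scaled MAD is floored at 0.5 kurtosis units -- the analogue of
  the scaled-MAD = 0 degeneracy rule -- because sub-0.5 differences are
  physiological montage texture, while genuine artifact channels exceed the
  median by tens.
* **Epoch rejection** iterates: reject epochs whose peak absolute amplitude
  exceeds median + 5 scaled MADs of the per-epoch peak distribution,
  recompute, stop at convergence or at `max_reject_fraction` (0.3), in which
  case the dataset is flagged high-artifact. A zero scaled MAD keeps
  everything.
* **ICA** is an explicit extension point (`ica =` argument), not an
  implemented step: component selection is inherently manual and cannot be
  specified reproducibly; the amplitude/kurtosis path above is the documented
  automatic cleaning route.
* Event onsets are remapped to the resampled rate by rounding to the nearest
  sample; epoch/window sample indices use half-open intervals with
  `floor(ms * fs / 1000)` starts, making the 1100 ms static window 275
  samples and the 2050 ms dynamic window 513 samples at 250 Hz.

## Spectral estimation

`band_psd()` computes a single Hann-tapered periodogram of the de-meaned
segment with density normalization (window power compensated). The windows
are too short for multi-segment averaging at 8 Hz resolution, so a single
taper is the right estimator here. The band summary is the *integral* of the
density over bins whose centre frequency lies in [8, 13] Hz divided by the
nominal 5 Hz bandwidth. A plain mean over band bins would not be comparable
across the two window lengths: the 1100 ms window's 0.909 Hz bin grid covers
5.45 Hz of the band while the 2050 ms window's 0.487 Hz grid covers 4.87 Hz,
which would bias every ratio by +0.049 log10 units even with no signal
change. The integral form is window-length invariant (the package's identity
tests rest on it) and keeps density units so both windows remain directly
comparable.

Per-trial cluster PSD is the channel-mean band density; the trial ratio is
the ratio of cluster PSDs, so `log10(ratio)` decomposes exactly into
`log10(psd_dynamic) - log10(psd_static)` -- the same quantities the paired
phase-contrast test consumes.

## Inference layer

* **CR1 clustered OLS** (`erd_ols()`): sandwich covariance with the
  `G/(G-1) * (N-1)/(N-k)` small-sample factor and t(G-1) reference. With one
  observation per cluster this is exactly HC1, which is the package's test
  oracle. CR1/t(G-1) is the conventional default among cluster-robust
  flavours; nothing in the analysis depends on the more aggressive CR2/CR3
  refinements at the G ~ 40-50 cluster counts targeted here.
* **Contrast effect size**: `d = contrast / pooled within-condition SD` of
  the outcome over the two contrasted levels (`d_type = "residual"` switches
  the denominator to the residual SD). There is no unique convention for a
  Cohen's d attached to a regression coefficient; this choice is explicit and
  configurable.
* **JZS Bayes factor** (`jzs_bf10()`): the Cauchy-prior marginal likelihood
  is evaluated through the normal-by-inverse-gamma mixture representation,
  integrating over the mixing variance in log space (integrand maximum
  located first, then adaptive quadrature of the shifted exponential). This
  keeps the computation finite for arbitrarily large |t| -- at t near 48 with
  thousands of pairs the naive integrand underflows double precision. The
  test oracle is an independent trapezoid quadrature over the standardized
  effect using the non-central t density.
* **Multiple testing**: none by default; contrasts report unadjusted p-values
  (a Holm correction can be applied to the emitted tables with
  `p.adjust`).

## Problem sizes used by the tests and the acceptance script

Simulation sizes are chosen to make the Monte-Carlo answers stable on a
single CPU: the recovery analysis uses 200 simulated sessions (20 batches of
10 participants) in the test suite and 100 sessions in the acceptance
script, on a 12-channel montage subset (both clusters, the frontal pair and
two spares); the type-I-error study uses 2000 replicates of a 40-participant
condition-level table; noiseless oracle runs use single-rhythm
configurations (see below) with the full 96-trial design. The montage subset
keeps the FFT work per session at about 4 seconds without changing any
analysis parameter.

## Design choices where the design was genuinely open

* **Mean-then-log**: condition aggregation averages kept ratios across block
  repetitions first and then takes log10. The reverse order would give the
  mean of log-ratios (a different estimand); the identity tests pin the
  implemented order.
* **Log base 10**: all indices and tolerances are stated in log10 units;
  `erd_index(log_base =)` makes the base explicit.
* **MAD screening scope**: per participant x cluster, so that
  between-participant power differences are not mistaken for outlying
  trials; a pooled scope is available (`mad_scope = "pooled"`).
* **Observation unit**: participant x character x emotion (up to 24 rows per
  participant per cluster), the granularity at which the condition design is
  balanced; trial-level analysis remains possible from the emitted
  `trial_power` table.
* **Go/No-Go ratio**: balanced 50/50 within block (ties toward Go),
  configurable -- the cue governs the post-stimulus mimicry period, which is
  never analyzed.
* **Single-rhythm oracle fixtures**: with both rhythms active, average
  referencing projects each rhythm onto the opposite cluster, and the
  finite-window interference between two narrowband tones adds zero-mean
  per-trial ratio noise. That term says nothing about the ERD estimator, so
  the exact-recovery oracles use mu-only or alpha-only configurations; the
  dual-rhythm generator is used unchanged in all statistical analyses, where
  the interference averages out.
* **Interpolation**: inverse-distance weighting over the 4 nearest good
  channels -- fully specifiable and testable by symmetry; spherical-spline
  interpolation would need a head model the schematic montage does not
  carry.

## Known limitations

* The in-band 1/f noise floor adds to both window PSDs and therefore shrinks
  recovered ERD toward zero; at the default SNR the shrinkage is about
  0.01--0.015 log10 units on the out-vs-in contrast (reported recoveries sit
  slightly inside the injected -0.169). At substantially lower SNR this bias
  grows and a noise-floor correction would be needed.
* Average referencing on small montage subsets mixes the two rhythms more
  strongly than on a full cap; correlation analyses between mu and alpha
  should use the full montage (the package's own mu-alpha tests do).
* The epoch-rejection and bad-channel procedures are robust-z stand-ins for
  tool-specific routines whose internal defaults are not public; thresholds
  match the conventional "5 SD" but the procedures are this package's own,
  documented definitions.
* EDF/EDF+ I/O is not provided; recordings, epochs and tables are exchanged
  as documented CSV/YAML containers (`run_pipeline()` writes the full set
  with a manifest).
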