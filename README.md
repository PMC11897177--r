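# muerd

Mu- and alpha-band event-related desynchronization (ERD) analysis for
within-subject EEG designs with dynamic face stimuli — and a synthetic EEG
generator with known ERD ground truth that makes every stage of the analysis
verifiable without access to raw study recordings.

## Who this is for

EEG researchers quantifying mu-rhythm suppression (central electrodes,
action/emotion observation) or alpha suppression (occipital electrodes,
visual attention) in paradigms where each trial contains a *static* baseline
phase followed by a *dynamic* stimulation phase — e.g. a neutral still image
that morphs into an emotional expression — and who analyze condition
contrasts across participants with cluster-robust regression and Bayes
factors.

## The statistic at its core

For each trial and electrode cluster *c*, let `P_static` and `P_dynamic` be
the mean 8–13 Hz power spectral density (Hann periodogram, density units) in
the 800–1900 ms and 1950–4000 ms windows of the 6000 ms stimulus. The
analysis unit is

    ERD index = log10( mean_trials( P_dynamic / P_static ) )

computed per participant × character × emotion × cluster after screening
trials whose ratio lies more than 3 scaled MADs from the participant ×
cluster median. Values `< 0` indicate desynchronization (ERD), `> 0`
synchronization (ERS), `0` no change. Inference uses OLS with CR1
cluster-robust standard errors at the participant level (t with G−1 df),
paired t-tests for the static-vs-dynamic phase contrast with paired Cohen's
d, and Jeffreys–Zellner–Siow Bayes factors (Cauchy scale √2/2).

The synthetic generator renders 64-channel (or subset) 512 Hz recordings —
1/f background plus two drifting 8–13 Hz oscillators projected over the
central and occipital clusters — in which the oscillator amplitude is
attenuated by a condition-dependent factor `a` during each trial's dynamic
window, so the true ERD index is exactly `2·log10(a)`.

## Worked example

Simulate a six-participant study at the default condition attenuations
(out-party 0.70, in-party and non-politician 0.85), run the full pipeline
(preprocess → band PSD ratios → MAD screening → condition aggregation), and
contrast conditions:

```r
library(muerd)
cfg <- sim_config(n_participants = 6, n_channels = 12)
res <- run_study(cfg, seed = 42)

fit <- erd_ols(mu ~ group, res$mu_alpha, cluster = "participant")
summary(fit)
#> Formula: mu ~ group
#> 144 observations, 6 clusters; t reference with 5 df
#>
#>                       Estimate Cluster SE  t value  Pr(>|t|)
#> (Intercept)         -0.1382963  0.0105549 -13.1026 4.622e-05 ***
#> groupnon_politician  0.0029784  0.0196461   0.1516    0.8854
#> groupout_party      -0.1458881  0.0082158 -17.7571 1.039e-05 ***

erd_contrast(fit, "group", "out_party", "in_party")
#> group: out_party - in_party
#>   beta = -0.1459, SE = 0.0082, t(5) = -17.757, p = 1.039e-05, d = -2.211

jzs_bf10(-17.757, 6)
#> JZS Bayes factor (Cauchy scale 0.707): BF10 = 1438, BF01 = 0.0006955
```

Reading the output: the intercept is the in-party mean ERD index (−0.138
log10 units, i.e. suppressed dynamic-phase power); the out-party contrast of
−0.146 recovers the injected ground-truth difference `2·log10(0.70/0.85) ≈
−0.169` up to the known noise-floor shrinkage and this run's sampling error;
the non-politician condition, generated at the in-party attenuation, shows no
difference. `res$ground_truth` carries each participant's true
`2·log10(a)` for direct comparison.

`run_pipeline(cfg, seed, out_dir)` writes every stage artifact (schedules,
ground truth, per-trial power, ERD indices, model tables) as CSV plus a
`manifest.json` with seed, version and file hashes; `inst/cli/muerd.R` is a
thin command-line wrapper (`simulate`, `preprocess`, `erd`, `stats`,
`run-all`, `power-sim`) over the same functions.

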