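Package: muerd
Title: Mu and Alpha Event-Related Desynchronization Analysis for EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and inference pipeline for mu- and
    alpha-band event-related desynchronization (ERD) in within-subject EEG
    designs with dynamic face stimuli. Provides a synthetic EEG generator
    with known condition-dependent ERD ground truth (1/f background,
    amplitude-modulated 8-13 Hz oscillators over central and occipital
    clusters, jittered Go/No-Go trial schedules), a preprocessing chain
    (FFT resampling, zero-phase band filtering, kurtosis-based bad-channel
    detection and interpolation, epoching, robust-z epoch rejection, average
    reference), band power spectral density ratios with scaled-MAD trial
    screening, and an inference layer with cluster-robust OLS contrasts,
    paired t-tests with Cohen's d, and Jeffreys-Zellner-Siow Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
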