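# Shared fixtures: small configurations and hand-built recordings/epochs.

# Small-montage config; single-oscillator variants serve as noiseless
# oracles (see the methods vignette: with both rhythms active, the
# finite-window interference between the two tones adds zero-mean per-trial
# ratio noise that is irrelevant to the estimator's correctness).
quick_cfg <- function(..., n_channels = 12) {
  sim_config(n_channels = n_channels, ...)
}

noiseless_cfg <- function(a, cluster = c("mu", "alpha"), n_blocks = 4,
                          n_channels = 12) {
  cluster <- match.arg(cluster)
  amp <- if (cluster == "mu") c(mu = 10, alpha = 0) else c(mu = 0, alpha = 12)
  sim_config(n_blocks = n_blocks, n_channels = n_channels,
             noise_sd = 0, subject_sd = 0, osc_amplitude = amp,
             attenuation = c(in_party = a, out_party = a,
                             non_politician = a))
}

# Recording built directly from a data matrix (channels from montage_64).
make_recording <- function(data, fs, events = NULL) {
  mont <- montage_64()[seq_len(nrow(data)), ]
  rownames(data) <- mont$label
  structure(list(data = data, fs = fs, channels = mont, events = events),
            class = "eeg_recording")
}

# Minimal event table with onsets (0-based samples).
make_events <- function(onsets, fs) {
  n <- length(onsets)
  data.frame(trial_index = seq_len(n), onset_sample = onsets,
             onset_ms = onsets / fs * 1000, fixation_ms = 2750,
             character_id = rep(c("in1", "out1", "non1"), length.out = n),
             group = rep(c("in_party", "out_party", "non_politician"),
                         length.out = n),
             emotion = rep(c("neutral", "happy", "angry"), length.out = n),
             block = 1L, cue = "go", stringsAsFactors = FALSE)
}

# Epochs object built directly from an array (epochs x channels x samples).
make_epochs <- function(data, fs, events = NULL) {
  n_ch <- dim(data)[2]
  mont <- montage_64()[seq_len(n_ch), ]
  dimnames(data) <- list(NULL, mont$label, NULL)
  if (is.null(events)) events <- make_events(seq_len(dim(data)[1]) - 1L, fs)
  structure(list(data = data, fs = fs, channels = mont, events = events,
                 provenance = list(interpolated = character(0),
                                   rejected = data.frame(
                                     trial_index = integer(0),
                                     reason = character(0)),
                                   n_input = dim(data)[1],
                                   high_artifact = FALSE)),
            class = "eeg_epochs")
}

# Independent fine-grid trapezoid oracle for the JZS Bayes factor,
# parameterized over the standardized effect delta (the implementation
# integrates over the g-mixture representation instead).
jzs_bf10_oracle <- function(t, n, r_scale = sqrt(2) / 2) {
  nu <- n - 1
  delta <- seq(-30, 30, length.out = 8001)
  num <- suppressWarnings(
    sum(stats::dt(t, nu, ncp = delta * sqrt(n)) *
          stats::dcauchy(delta, 0, r_scale))) * (delta[2] - delta[1])
  num / stats::dt(t, nu)
}

run_session_erd <- function(cfg, seed) {
  s <- build_schedule(cfg, seed)
  sim <- synthesize_recording(s, cfg, seed + 1000L)
  erd_index(trial_power(preprocess_recording(sim$recording)))
}
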