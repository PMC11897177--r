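#' Simulation configuration
#'
#' Builds the configuration object for the synthetic EEG generator. Defaults
#' reproduce the study design the package targets: a 3 (emotion) x 3
#' (character group) within-subject Go/No-Go paradigm with 8 characters
#' (2 in-party, 2 out-party, 4 non-politician), 3 emotions, 4 blocks of 24
#' trials (96 trials per participant), 512 Hz sampling on a 64-channel 10-20
#' montage, a 2500--3000 ms jittered fixation, and a 6000 ms stimulus whose
#' middle 2000 ms carries the dynamic expression during which the 8--13 Hz
#' oscillators are attenuated by a condition-dependent factor.
#'
#' @param n_participants Number of simulated participants.
#' @param n_blocks Number of blocks; each block presents every
#'   (character, emotion) pair exactly once.
#' @param characters data.frame with columns `character_id` and `group`
#'   (levels `in_party`, `out_party`, `non_politician`).
#' @param emotions Character vector of emotion conditions.
#' @param fs Sampling rate in Hz.
#' @param n_channels Montage size (subset of [montage_64()]).
#' @param fixation_range Fixation-cross duration interval, ms.
#' @param stimulus_dur Stimulus duration, ms.
#' @param dynamic_window Interval of the dynamic expression within the
#'   stimulus, ms (half-open).
#' @param cue_dur Durations of the empty-circle and Go/No-Go cue periods, ms.
#' @param attenuation Named numeric vector in (0, 1]: amplitude attenuation of
#'   the band oscillators during the dynamic window, per character group (or
#'   per `"group:emotion"` key for emotion-specific effects). An attenuation
#'   `a` implies a true log10 power ratio of `2*log10(a)`.
#' @param subject_sd Between-participant SD of the true log10 power ratio
#'   (log10 units), applied as an independent lognormal jitter on the
#'   attenuation per participant, condition and oscillator. Set 0 for exact
#'   noiseless oracles.
#' @param osc_freq Named vector `c(mu = , alpha = )`: centre frequencies of
#'   the two oscillators, Hz. Defaults keep the rhythms spectrally separable
#'   within 8--13 Hz (sensorimotor mu typically peaks slightly higher than
#'   posterior alpha), which keeps their cross-terms out of the short-window
#'   band PSD estimates.
#' @param freq_drift_sd SD of the slow Ornstein-Uhlenbeck frequency drift,
#'   Hz; each oscillator's instantaneous frequency is clipped to its centre
#'   +/- `2 * freq_drift_sd` (and to 8--13 Hz).
#' @param osc_amplitude Named vector `c(mu = , alpha = )`, baseline oscillator
#'   amplitude in microvolts at the cluster electrodes.
#' @param noise_exponent Spectral exponent of the 1/f background noise.
#' @param noise_sd SD of the background noise per channel, microvolts.
#' @param leakage_width Width (head-radius units) of the Gaussian spatial
#'   kernel projecting each oscillator onto the scalp; larger values leak
#'   central activity into occipital channels and vice versa.
#' @param ramp_ms Raised-cosine on/off ramp length flanking the attenuated
#'   window, ms. Ramps sit outside the dynamic window so the full video
#'   period carries the attenuated amplitude.
#' @param artifact_rate Blink/muscle artifact rate, events per minute, on the
#'   frontal channels. 0 disables artifacts.
#' @param artifact_amplitude Peak artifact amplitude, microvolts.
#' @param go_ratio Proportion of Go cues within each block (ties broken
#'   toward Go).
#' @param tail_ms Silent padding after the last trial, ms.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 1L,
                       n_blocks = 4L,
                       characters = default_characters(),
                       emotions = c("neutral", "happy", "angry"),
                       fs = 512,
                       n_channels = 64L,
                       fixation_range = c(2500, 3000),
                       stimulus_dur = 6000,
                       dynamic_window = c(2000, 4000),
                       cue_dur = c(2000, 3000),
                       attenuation = c(in_party = 0.85, out_party = 0.70,
                                       non_politician = 0.85),
                       subject_sd = 0.08,
                       osc_freq = c(mu = 11.6, alpha = 9.4),
                       freq_drift_sd = 0.5,
                       osc_amplitude = c(mu = 10, alpha = 12),
                       noise_exponent = 1,
                       noise_sd = 3,
                       leakage_width = 0.30,
                       ramp_ms = 100,
                       artifact_rate = 0,
                       artifact_amplitude = 200,
                       go_ratio = 0.5,
                       tail_ms = 1000) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_blocks = as.integer(n_blocks),
              characters = characters, emotions = emotions, fs = fs,
              n_channels = as.integer(n_channels),
              fixation_range = fixation_range, stimulus_dur = stimulus_dur,
              dynamic_window = dynamic_window, cue_dur = cue_dur,
              attenuation = attenuation, subject_sd = subject_sd,
              osc_freq = osc_freq, freq_drift_sd = freq_drift_sd,
              osc_amplitude = osc_amplitude, noise_exponent = noise_exponent,
              noise_sd = noise_sd, leakage_width = leakage_width,
              ramp_ms = ramp_ms, artifact_rate = artifact_rate,
              artifact_amplitude = artifact_amplitude, go_ratio = go_ratio,
              tail_ms = tail_ms)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default character set: 2 in-party, 2 out-party, 4 non-politicians
#' @return data.frame with columns `character_id`, `group`.
#' @export
default_characters <- function() {
  data.frame(
    character_id = c("in1", "in2", "out1", "out2",
                     "non1", "non2", "non3", "non4"),
    group = c("in_party", "in_party", "out_party", "out_party",
              rep("non_politician", 4)),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  if (!is.data.frame(cfg$characters) || nrow(cfg$characters) == 0 ||
      !all(c("character_id", "group") %in% names(cfg$characters)))
    stop("invalid config: 'characters' must be a non-empty data.frame with ",
         "character_id and group columns", call. = FALSE)
  if (anyDuplicated(cfg$characters$character_id))
    stop("invalid config: duplicated character_id", call. = FALSE)
  if (length(cfg$emotions) == 0)
    stop("invalid config: empty emotion set", call. = FALSE)
  if (cfg$n_blocks < 1L)
    stop("invalid config: need at least one block", call. = FALSE)
  if (length(cfg$fixation_range) != 2 || any(cfg$fixation_range <= 0) ||
      diff(cfg$fixation_range) < 0)
    stop("invalid config: fixation_range must be a positive interval",
         call. = FALSE)
  if (cfg$dynamic_window[1] < 0 || cfg$dynamic_window[2] > cfg$stimulus_dur ||
      diff(cfg$dynamic_window) <= 0)
    stop("invalid config: dynamic_window must lie inside [0, stimulus_dur)",
         call. = FALSE)
  if (any(cfg$attenuation <= 0) || any(cfg$attenuation > 1))
    stop("invalid config: attenuation factors must be in (0, 1]",
         call. = FALSE)
  groups <- unique(cfg$characters$group)
  missing_att <- setdiff(groups, c(names(cfg$attenuation),
                                   sub(":.*$", "", names(cfg$attenuation))))
  if (length(missing_att))
    stop("invalid config: no attenuation for group(s) ",
         paste(missing_att, collapse = ", "), call. = FALSE)
  if (cfg$fs <= 0 || cfg$noise_sd < 0 || cfg$subject_sd < 0 ||
      cfg$artifact_rate < 0)
    stop("invalid config: negative rate/scale parameter", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d participant(s), %d block(s) x %d characters x %d emotions = %d trials\n",
              x$n_participants, x$n_blocks, nrow(x$characters),
              length(x$emotions),
              x$n_blocks * nrow(x$characters) * length(x$emotions)))
  cat(sprintf("  fs %g Hz, %d channels; fixation %g-%g ms; stimulus %g ms (dynamic %g-%g ms)\n",
              x$fs, x$n_channels, x$fixation_range[1], x$fixation_range[2],
              x$stimulus_dur, x$dynamic_window[1], x$dynamic_window[2]))
  cat("  attenuation:", paste(sprintf("%s=%.2f", names(x$attenuation),
                                      x$attenuation), collapse = ", "), "\n")
  invisible(x)
}

# Attenuation lookup for a (group, emotion) pair: an exact "group:emotion"
# key wins over the group-level key.
attenuation_for <- function(cfg, group, emotion) {
  key <- paste(group, emotion, sep = ":")
  a <- cfg$attenuation[key]
  if (is.na(a)) a <- cfg$attenuation[group]
  unname(a)
}
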