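#' Synthesize a raw EEG recording with known ERD ground truth
#'
#' Renders a multichannel recording for one participant from a trial
#' schedule: per-channel 1/f background noise plus two amplitude-modulated
#' 8--13 Hz oscillators -- a mu oscillator projecting onto the scalp with
#' Gaussian weights peaking at the central electrodes (C3, C1, Cz, C2, C4)
#' and an alpha oscillator peaking occipitally (O1, Oz, O2). During each
#' trial's dynamic window the oscillator amplitude is multiplied by the
#' condition's attenuation factor (raised-cosine ramps of `ramp_ms` flank the
#' window), so the true log10 band-power ratio of the condition is
#' `2*log10(a)`. Oscillator frequency drifts slowly inside 8--13 Hz
#' (Ornstein-Uhlenbeck around `osc_freq`). Optional high-amplitude
#' low-frequency transients (blinks) arrive as a Poisson process on the
#' frontal channels. Identical (schedule, cfg, seed) gives bit-identical
#' output.
#'
#' @param schedule A [build_schedule()] result.
#' @param cfg The [sim_config()] used to build the schedule.
#' @param seed Integer seed.
#' @param participant Participant identifier carried into the ground truth.
#' @param n_samples Optional recording length (samples); must cover the full
#'   schedule, otherwise a length-mismatch error is raised. Default: last
#'   trial end plus `tail_ms`.
#' @return list with elements `recording` (class `eeg_recording`: `data`
#'   channels x samples matrix in microvolts, `fs`, `channels` montage
#'   data.frame, `events` = schedule) and `ground_truth` (data.frame:
#'   `participant`, `cluster`, `group`, `emotion`, `attenuation`,
#'   `true_log_ratio = 2*log10(attenuation)`).
#' @export
synthesize_recording <- function(schedule, cfg, seed = 1L,
                                 participant = "p1", n_samples = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.data.frame(schedule) || nrow(schedule) == 0)
    stop("schedule must be a non-empty trial schedule", call. = FALSE)
  fs <- cfg$fs
  trial_span <- (cfg$stimulus_dur + sum(cfg$cue_dur)) * fs / 1000
  need <- max(schedule$onset_sample) + trial_span + cfg$tail_ms * fs / 1000
  need <- as.integer(ceiling(need))
  if (is.null(n_samples)) {
    # round up to 256 * (5-smooth k): keeps FFT lengths smooth here and
    # after 512 -> 250 Hz resampling (n * 125/256 stays 5-smooth)
    n_samples <- 256L * stats::nextn(ceiling(need / 256), c(2L, 3L, 5L))
  }
  if (n_samples < need)
    stop("length mismatch: schedule extends past the requested recording ",
         "length (need ", need, " samples, got ", n_samples, ")",
         call. = FALSE)
  set.seed(as.integer(seed))

  mont <- montage_64(cfg$n_channels)
  n_ch <- nrow(mont)

  # per-participant true attenuation: condition value with independent
  # lognormal jitter per oscillator (subject_sd in log10 power-ratio units)
  conds <- expand.grid(group = unique(cfg$characters$group),
                       emotion = cfg$emotions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(c("mu_central", "alpha_occipital"),
    function(cl) {
      a0 <- mapply(attenuation_for, conds$group, conds$emotion,
                   MoreArgs = list(cfg = cfg))
      eps <- stats::rnorm(nrow(conds), 0, cfg$subject_sd)
      a <- pmin(1, a0 * 10^(eps / 2))
      data.frame(participant = participant, cluster = cl,
                 group = conds$group, emotion = conds$emotion,
                 attenuation = a, true_log_ratio = 2 * log10(a),
                 stringsAsFactors = FALSE)
    }))
  rownames(truth) <- NULL

  freq <- if (length(cfg$osc_freq) == 1)
    c(mu = unname(cfg$osc_freq), alpha = unname(cfg$osc_freq)) else
    cfg$osc_freq
  osc <- list(
    mu_central = list(amp = cfg$osc_amplitude[["mu"]],
                      f0 = freq[["mu"]], centers = mu_channels()),
    alpha_occipital = list(amp = cfg$osc_amplitude[["alpha"]],
                           f0 = freq[["alpha"]], centers = alpha_channels())
  )

  # Channels are assembled in the frequency domain (oscillator source
  # spectra + directly synthesized hermitian 1/f noise spectra) and
  # materialized by real-pair inverse FFTs; the per-channel spectra are
  # cached on the recording so that downstream FFT resampling/filtering can
  # skip the forward transform. Results are identical to time-domain
  # assembly.
  S <- matrix(0i, nrow = n_samples, ncol = n_ch)
  for (cl in names(osc)) {
    f <- ou_frequency(n_samples, fs, osc[[cl]]$f0, cfg$freq_drift_sd)
    phase <- cumsum(2 * pi * f / fs) + stats::runif(1, 0, 2 * pi)
    env <- attenuation_envelope(n_samples, fs, schedule, cfg,
                                truth[truth$cluster == cl, ])
    SRC <- stats::fft(osc[[cl]]$amp * env * sin(phase))
    w <- spatial_weights(mont, osc[[cl]]$centers, cfg$leakage_width)
    for (i in seq_len(n_ch)) if (w[i] > 1e-10) S[, i] <- S[, i] + w[i] * SRC
  }
  if (cfg$noise_sd > 0)
    S <- S + hermitian_noise_spectra(n_samples, n_ch, cfg$noise_exponent,
                                     cfg$noise_sd)
  data <- materialize_spectra(S)
  rownames(data) <- mont$label
  keep_cache <- TRUE
  if (cfg$artifact_rate > 0) {
    data <- add_artifacts(data, mont, fs, cfg$artifact_rate,
                          cfg$artifact_amplitude)
    keep_cache <- FALSE   # time-domain edits invalidate the spectra
  }
  rec <- structure(list(data = data, fs = fs, channels = mont,
                        events = schedule),
                   class = "eeg_recording")
  if (keep_cache) attr(rec, "spectrum_cache") <- S
  list(recording = rec, ground_truth = truth)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

# Ornstein-Uhlenbeck frequency drift, clipped to f0 +/- 1.5*drift_sd and to
# the 8-13 Hz band. The clip keeps the two oscillators' drift ranges disjoint
# (no shared instantaneous frequency, which would create coherent
# cross-terms in short-window PSDs) and away from the band edges (where
# spectral leakage of the short static window would escape the band).
# Discretized as AR(1) with 1 s correlation time and stationary sd drift_sd.
ou_frequency <- function(n, fs, f0, drift_sd) {
  if (drift_sd <= 0) return(rep(f0, n))
  phi <- exp(-1 / fs)
  innov_sd <- drift_sd * sqrt(1 - phi^2)
  d <- stats::filter(stats::rnorm(n, 0, innov_sd), phi, "recursive",
                     init = stats::rnorm(1, 0, drift_sd))
  d <- pmin(1.5 * drift_sd, pmax(-1.5 * drift_sd, as.numeric(d)))
  pmin(13, pmax(8, f0 + d))
}

# Amplitude envelope: 1 at baseline, the trial's true attenuation over the
# dynamic window, with raised-cosine ramps of ramp_ms placed OUTSIDE the
# window (down-ramp ending at window start, up-ramp starting at window end)
# so the whole video window carries the attenuated amplitude.
attenuation_envelope <- function(n, fs, schedule, cfg, truth_cl) {
  env <- rep(1, n)
  n_ramp <- max(1L, round(cfg$ramp_ms * fs / 1000))
  u <- (seq_len(n_ramp) - 0.5) / n_ramp
  down <- 0.5 * (1 + cos(pi * u))   # 1 -> 0
  up <- rev(down)                   # 0 -> 1
  key <- paste(truth_cl$group, truth_cl$emotion)
  a_of <- truth_cl$attenuation[match(paste(schedule$group, schedule$emotion),
                                     key)]
  w1 <- round(cfg$dynamic_window[1] * fs / 1000)
  w2 <- round(cfg$dynamic_window[2] * fs / 1000)
  for (t in seq_len(nrow(schedule))) {
    a <- a_of[t]
    if (a >= 1) next
    on <- schedule$onset_sample[t]
    flat <- (on + w1):(on + w2 - 1L) + 1L  # 1-based
    env[flat] <- a
    dn_idx <- (on + w1 - n_ramp):(on + w1 - 1L) + 1L
    env[dn_idx] <- a + (1 - a) * down
    up_idx <- (on + w2):(on + w2 + n_ramp - 1L) + 1L
    env[up_idx] <- a + (1 - a) * up
  }
  env
}

# Gaussian spatial projection of an oscillator onto the montage, normalized
# so the mean weight over the oscillator's own cluster electrodes is 1.
spatial_weights <- function(mont, centers, width) {
  idx <- match(centers, mont$label)
  idx <- idx[!is.na(idx)]
  if (!length(idx))
    stop("montage lacks all cluster electrodes: ",
         paste(centers, collapse = ", "), call. = FALSE)
  w <- rep(0, nrow(mont))
  for (j in idx) {
    d2 <- (mont$x - mont$x[j])^2 + (mont$y - mont$y[j])^2
    w <- w + exp(-d2 / (2 * width^2))
  }
  w / mean(w[idx])
}

# Hermitian spectra of independent 1/f^exponent Gaussian noise channels in
# fft() convention (E|X_k|^2 = n * sigma_k^2), scaled so the time-domain
# variance is sd_uv^2 in expectation. Zero-mean by construction (DC bin = 0);
# n must be even. Returns an n x n_ch complex matrix.
hermitian_noise_spectra <- function(n, n_ch, exponent, sd_uv) {
  m <- n %/% 2L
  fidx <- seq_len(m)                       # cycles per record, 1 .. n/2
  w <- fidx^(-exponent)                    # power shape
  # total expected time variance = (1/n^2) * sum_k E|X_k|^2
  # bins 1..m-1 appear twice (conjugate pair), the Nyquist bin once
  tot <- 2 * sum(w[-m]) + w[m]
  g <- sqrt(n^2 * sd_uv^2 / tot) * sqrt(w)  # per-bin amplitude scale
  g <- g * c(rep(sqrt(0.5), m - 1L), 1)     # split power re/im; Nyquist real
  zr <- matrix(stats::rnorm(m * n_ch), m, n_ch)
  zi <- matrix(stats::rnorm(m * n_ch), m, n_ch)
  zi[m, ] <- 0                              # Nyquist bin is real
  X <- matrix(0i, n, n_ch)
  X[2:(m + 1L), ] <- g * complex(real = zr, imaginary = zi)
  X[n:(m + 2L), ] <- Conj(X[2:m, , drop = FALSE])
  X
}

hermitian_noise_spectrum <- function(n, exponent, sd_uv) {
  hermitian_noise_spectra(n, 1L, exponent, sd_uv)[, 1]
}

#' 1/f background noise
#'
#' One realization of Gaussian noise with a `1/f^exponent` power spectrum,
#' synthesized in the frequency domain; `sd_uv` is the standard deviation in
#' expectation (per-realization sd varies slightly, as for any finite
#' record).
#'
#' @param n Number of samples (even).
#' @param exponent Spectral exponent (0 = white).
#' @param sd_uv Nominal standard deviation, microvolts.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, exponent = 1, sd_uv = 1) {
  if (n %% 2L) stop("n must be even", call. = FALSE)
  if (exponent == 0) return(stats::rnorm(n, 0, sd_uv))
  Re(stats::fft(hermitian_noise_spectrum(n, exponent, sd_uv),
                inverse = TRUE)) / n
}

# Inverse-transform a matrix of hermitian channel spectra (columns) into a
# channels x samples real matrix, two channels per complex FFT.
materialize_spectra <- function(S) {
  n <- nrow(S); n_ch <- ncol(S)
  out <- matrix(0, nrow = n_ch, ncol = n)
  i <- 1L
  while (i <= n_ch) {
    if (i + 1L <= n_ch) {
      y <- stats::fft(S[, i] + 1i * S[, i + 1L], inverse = TRUE) / n
      out[i, ] <- Re(y)
      out[i + 1L, ] <- Im(y)
      i <- i + 2L
    } else {
      out[i, ] <- Re(stats::fft(S[, i], inverse = TRUE)) / n
      i <- i + 1L
    }
  }
  out
}

# Poisson blink-like transients: 400 ms raised-cosine pulses on the frontal
# channels (Fp1/Fp2, plus AF3/AF4 at reduced gain when present).
add_artifacts <- function(data, mont, fs, rate_per_min, amplitude) {
  n <- ncol(data)
  n_art <- stats::rpois(1, rate_per_min * n / fs / 60)
  if (n_art == 0) return(data)
  dur <- round(0.4 * fs)
  pulse <- amplitude * 0.5 * (1 - cos(2 * pi * seq_len(dur) / dur))
  targets <- list(Fp1 = 1, Fp2 = 1, AF3 = 0.4, AF4 = 0.4)
  starts <- sort(sample.int(n - dur, n_art))
  for (s in starts) {
    idx <- s:(s + dur - 1L)
    for (lab in names(targets)) {
      i <- match(lab, mont$label)
      if (!is.na(i)) data[i, idx] <- data[i, idx] + targets[[lab]] * pulse
    }
  }
  data
}
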