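#' Frequency band and phase windows
#'
#' `erd_band()` is the mu/alpha analysis band (8--13 Hz). `phase_windows()`
#' defines the two analysis sub-epochs of the 6000 ms stimulus: a static
#' window of 800--1900 ms (1100 ms, inside the neutral still image that
#' serves as within-trial baseline) and a dynamic window of 1950--4000 ms
#' (2050 ms, covering the moving expression).
#'
#' @param lo,hi Band edges, Hz.
#' @param static,dynamic Half-open ms intervals within the epoch.
#' @return Named list.
#' @export
erd_band <- function(lo = 8, hi = 13) {
  if (!(lo > 0 && lo < hi)) stop("invalid band: need 0 < lo < hi",
                                 call. = FALSE)
  list(lo = lo, hi = hi)
}

#' @rdname erd_band
#' @export
phase_windows <- function(static = c(800, 1900), dynamic = c(1950, 4000)) {
  if (diff(static) <= 0 || diff(dynamic) <= 0 || static[2] > dynamic[1])
    stop("invalid windows: must be disjoint with static before dynamic",
         call. = FALSE)
  list(static = static, dynamic = dynamic)
}

#' Extract the static and dynamic phase segments of one epoch
#'
#' Windows are half-open sample intervals with start index
#' `floor(ms * fs / 1000)`; at 250 Hz the defaults give 275 (static) and 513
#' (dynamic) samples.
#'
#' @param epoch channels x samples matrix for one epoch.
#' @param fs Sampling rate, Hz.
#' @param windows A [phase_windows()].
#' @return list with `static` and `dynamic` channel x sample matrices.
#' @export
extract_phase_windows <- function(epoch, fs, windows = phase_windows()) {
  n <- ncol(epoch)
  cut1 <- function(w) {
    s0 <- floor(w[1] * fs / 1000)
    s1 <- floor(w[2] * fs / 1000)
    if (s0 < 0 || s1 > n)
      stop("invalid window: [", w[1], ", ", w[2], ") ms lies outside the ",
           "epoch", call. = FALSE)
    epoch[, (s0 + 1):s1, drop = FALSE]
  }
  list(static = cut1(windows$static), dynamic = cut1(windows$dynamic))
}

#' Band-average power spectral density (Hann periodogram)
#'
#' Computes the one-sided Hann-windowed periodogram of the de-meaned segment
#' with density normalization (window power compensated), and returns the
#' band-average density: the integral of the PSD over bins whose centre
#' frequency lies in `[lo, hi]`, divided by the nominal bandwidth `hi - lo`.
#' Averaging the integral (rather than the raw bin mean) makes the estimate
#' invariant to the segment length, so the 1100 ms and 2050 ms windows are
#' directly comparable in microvolt^2/Hz.
#'
#' @param segment Numeric vector, or channels x samples matrix (channels are
#'   averaged after the per-channel PSD).
#' @param band An [erd_band()].
#' @param fs Sampling rate, Hz.
#' @return Band-average PSD, microvolt^2/Hz.
#' @export
band_psd <- function(segment, band = erd_band(), fs) {
  if (is.matrix(segment))
    return(mean(band_psd_cols(t(segment), band, fs)))
  unname(band_psd_cols(matrix(segment, ncol = 1), band, fs))
}

# Band-average Hann-periodogram density of each column of a samples x
# signals matrix (one mvfft for all signals).
band_psd_cols <- function(m, band, fs) {
  n <- nrow(m)
  if (n < 2 * fs / band$lo)
    stop("segment too short: need at least 2 cycles of ", band$lo, " Hz",
         call. = FALSE)
  x <- sweep(m, 2, colMeans(m))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  U <- sum(w^2)
  X <- stats::mvfft(x * w)
  nk <- floor(n / 2)
  freqs <- (1:nk) * fs / n
  sel <- which(freqs >= band$lo & freqs <= band$hi)
  if (!length(sel)) stop("no PSD bins inside the band", call. = FALSE)
  pxx <- 2 * Mod(X[sel + 1L, , drop = FALSE])^2 / (fs * U)  # one-sided
  if (n %% 2 == 0 && nk %in% sel)
    pxx[match(nk, sel), ] <- pxx[match(nk, sel), ] / 2  # Nyquist not doubled
  df <- fs / n
  colSums(pxx) * df / (band$hi - band$lo)
}

#' Dynamic/static PSD ratio for one trial
#'
#' @param psd_dynamic,psd_static Band-average PSDs; both must be positive.
#' @return `psd_dynamic / psd_static`.
#' @export
trial_ratio <- function(psd_dynamic, psd_static) {
  if (any(!is.finite(c(psd_dynamic, psd_static))) ||
      any(c(psd_dynamic, psd_static) <= 0))
    stop("corrupt trial: nonpositive or non-finite PSD", call. = FALSE)
  psd_dynamic / psd_static
}

#' Scaled-MAD outlier screening
#'
#' Keeps values within `k` scaled MADs (1.4826 x median absolute deviation)
#' of the median. A scaled MAD of 0 keeps everything; fewer than 4 values
#' skips filtering with a warning. Single pass; invariant to input order.
#'
#' @param x Numeric vector (typically PSD ratios of one participant x
#'   cluster).
#' @param k Threshold in scaled-MAD units (default 3).
#' @return Logical keep mask, same length as `x`.
#' @examples
#' mad_filter(c(0.9, 1.0, 1.1, 1.0, 5.0))  # rejects 5.0
#' @export
mad_filter <- function(x, k = 3) {
  if (length(x) < 4) {
    warning("fewer than 4 values: MAD screening skipped")
    return(rep(TRUE, length(x)))
  }
  s <- stats::mad(x)
  if (s == 0) return(rep(TRUE, length(x)))
  abs(x - stats::median(x)) <= k * s
}

#' Per-trial, per-cluster band power and ratio
#'
#' For every epoch and electrode cluster: band-average PSD of the static and
#' dynamic phase segments (cluster channels averaged), their ratio, and the
#' per-phase log10 band PSDs whose difference equals log10(ratio) exactly.
#' Trials with a nonpositive PSD are flagged `kept = FALSE` with the reason.
#'
#' @param ep An `eeg_epochs`.
#' @param clusters Named list of channel-label vectors
#'   (default [default_clusters()]).
#' @param band An [erd_band()].
#' @param windows A [phase_windows()].
#' @param participant Participant id column value.
#' @return data.frame: `participant`, `trial_index`, `character_id`, `group`,
#'   `emotion`, `block`, `cue`, `cluster`, `psd_static`, `psd_dynamic`,
#'   `ratio`, `log_psd_static`, `log_psd_dynamic`, `kept`.
#' @export
trial_power <- function(ep, clusters = default_clusters(),
                        band = erd_band(), windows = phase_windows(),
                        participant = "p1") {
  stopifnot(inherits(ep, "eeg_epochs"))
  labels <- dimnames(ep$data)[[2]]
  for (cl in names(clusters))
    if (!all(clusters[[cl]] %in% labels))
      stop("cluster ", cl, " channels missing from the montage: ",
           paste(setdiff(clusters[[cl]], labels), collapse = ", "),
           call. = FALSE)
  n_ep <- dim(ep$data)[1]
  fs <- ep$fs
  win_idx <- function(w) {
    s0 <- floor(w[1] * fs / 1000); s1 <- floor(w[2] * fs / 1000)
    if (s0 < 0 || s1 > dim(ep$data)[3])
      stop("invalid window: lies outside the epoch", call. = FALSE)
    (s0 + 1):s1
  }
  idx_s <- win_idx(windows$static)
  idx_d <- win_idx(windows$dynamic)
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- names(clusters)[ci]
    ch <- match(clusters[[cl]], labels)
    cluster_psd <- function(t_idx) {
      # samples x (epoch * channel) matrix -> per-epoch channel-mean density
      seg <- ep$data[, ch, t_idx, drop = FALSE]
      m <- matrix(aperm(seg, c(3, 1, 2)), nrow = length(t_idx))
      p <- band_psd_cols(m, band, fs)
      rowMeans(matrix(p, nrow = n_ep))
    }
    ps <- cluster_psd(idx_s)
    pd <- cluster_psd(idx_d)
    ok <- is.finite(ps) & is.finite(pd) & ps > 0 & pd > 0
    out[[ci]] <- data.frame(
      participant = participant, trial_index = ep$events$trial_index,
      character_id = ep$events$character_id, group = ep$events$group,
      emotion = ep$events$emotion, block = ep$events$block,
      cue = ep$events$cue, cluster = cl,
      psd_static = ps, psd_dynamic = pd,
      ratio = ifelse(ok, pd / ps, NA_real_),
      log_psd_static = ifelse(ok, log10(ps), NA_real_),
      log_psd_dynamic = ifelse(ok, log10(pd), NA_real_),
      kept = ok, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$trial_index, out$cluster), ]
  rownames(out) <- NULL
  out
}

#' Screen trials and aggregate to condition-level ERD indices
#'
#' Applies [mad_filter()] to the PSD ratios per participant x cluster, then
#' aggregates the kept trials per participant x character x emotion x
#' cluster: mean of the kept ratios across block repetitions, then log10
#' (mean-then-log). Negative values indicate ERD, positive values ERS, 0 no
#' change. Cells with zero kept trials are emitted with `value = NA` and a
#' warning.
#'
#' @param tp A [trial_power()] table (one or more participants).
#' @param mad_k Scaled-MAD threshold (default 3); `Inf` disables screening.
#' @param mad_scope `"participant"` (default: screen within participant x
#'   cluster) or `"pooled"` (screen per cluster across participants).
#' @param log_base Base of the log transform (default 10).
#' @return data.frame of class `erd_index`: `participant`, `character_id`,
#'   `group`, `emotion`, `cluster`, `value`, `n_trials_kept`.
#' @export
erd_index <- function(tp, mad_k = 3, mad_scope = c("participant", "pooled"),
                      log_base = 10) {
  mad_scope <- match.arg(mad_scope)
  # the design grid of cells, before any screening (missing cells are
  # emitted as NA so both clusters always share the same row set)
  grid <- unique(tp[, c("participant", "character_id", "group", "emotion",
                        "cluster")])
  tp <- tp[tp$kept & is.finite(tp$ratio), , drop = FALSE]
  scope <- if (mad_scope == "participant")
    interaction(tp$participant, tp$cluster, drop = TRUE)
  else factor(tp$cluster)
  keep <- unsplit(lapply(split(tp$ratio, scope), mad_filter, k = mad_k),
                  scope)
  tp <- tp[keep, , drop = FALSE]
  agg <- stats::aggregate(ratio ~ participant + character_id + group +
                            emotion + cluster, data = tp,
                          FUN = function(x) c(m = mean(x), n = length(x)))
  agg <- data.frame(agg[, c("participant", "character_id", "group",
                            "emotion", "cluster")],
                    value = log(agg$ratio[, "m"], base = log_base),
                    n_trials_kept = as.integer(agg$ratio[, "n"]),
                    stringsAsFactors = FALSE)
  out <- merge(grid, agg, all.x = TRUE, sort = FALSE)
  out$n_trials_kept[is.na(out$n_trials_kept)] <- 0L
  if (anyNA(out$value))
    warning(sum(is.na(out$value)), " cell(s) have no kept trials")
  out <- out[order(out$participant, out$cluster, out$character_id,
                   out$emotion), ]
  rownames(out) <- NULL
  class(out) <- c("erd_index", "data.frame")
  out
}

#' Combine mu and alpha ERD indices into one analysis table
#'
#' One row per participant x character x emotion with the mu-cluster and
#' alpha-cluster log power ratios side by side, ready for the inference layer
#' (e.g. clustered OLS of `mu` on condition dummies with `alpha` as
#' covariate, or the mu-alpha correlation).
#'
#' @param erd An [erd_index()] table containing both clusters.
#' @param mu_cluster,alpha_cluster Cluster names.
#' @return data.frame: `participant`, `character_id`, `group`, `emotion`,
#'   `mu`, `alpha`.
#' @export
mu_alpha_table <- function(erd, mu_cluster = "mu_central",
                           alpha_cluster = "alpha_occipital") {
  m <- erd[erd$cluster == mu_cluster, , drop = FALSE]
  a <- erd[erd$cluster == alpha_cluster, , drop = FALSE]
  key <- function(d) paste(d$participant, d$character_id, d$emotion)
  if (nrow(m) != nrow(a) || !setequal(key(m), key(a)))
    stop("alignment error: mu and alpha rows do not match", call. = FALSE)
  a <- a[match(key(m), key(a)), ]
  data.frame(m[, c("participant", "character_id", "group", "emotion")],
             mu = m$value, alpha = a$value, stringsAsFactors = FALSE)
}
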