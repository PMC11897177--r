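#' Standard 64-channel 10-10 montage with idealized 2-D positions
#'
#' Returns the channel set emulating a 64-electrode cap placed according to
#' the international 10-20/10-10 system, with idealized 2-D head-plane
#' coordinates (unit head radius, nose up). Positions are schematic: they are
#' used for distance-based operations (bad-channel interpolation, spatial
#' leakage kernels in the simulator), not for topographic plotting fidelity.
#'
#' @param n_channels Number of channels to keep (10--64). Subsets always
#'   retain the analysis clusters (C3, C1, Cz, C2, C4; O1, Oz, O2) and the
#'   frontal pair Fp1/Fp2 used for simulated blink artifacts, then fill with
#'   the remaining labels in montage order.
#' @return A data.frame with columns `label`, `x`, `y`.
#' @examples
#' head(montage_64())
#' montage_64(12)$label
#' @export
montage_64 <- function(n_channels = 64) {
  rows <- list(
    Fp = list(y = 0.90, labels = c("Fp1", "Fpz", "Fp2"), lat = c(-0.30, 0, 0.30)),
    AF = list(y = 0.70, labels = c("AF7", "AF3", "AFz", "AF4", "AF8"),
              lat = c(-0.60, -0.30, 0, 0.30, 0.60)),
    F  = list(y = 0.45, labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
              lat = c(-0.80, -0.60, -0.40, -0.20, 0, 0.20, 0.40, 0.60, 0.80)),
    FC = list(y = 0.22, labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
              lat = c(-0.90, -0.68, -0.45, -0.22, 0, 0.22, 0.45, 0.68, 0.90)),
    C  = list(y = 0.00, labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
              lat = c(-1.00, -0.75, -0.50, -0.25, 0, 0.25, 0.50, 0.75, 1.00)),
    CP = list(y = -0.22, labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
              lat = c(-0.90, -0.68, -0.45, -0.22, 0, 0.22, 0.45, 0.68, 0.90)),
    P  = list(y = -0.45, labels = c("P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10"),
              lat = c(-1.00, -0.80, -0.60, -0.40, -0.20, 0, 0.20, 0.40, 0.60, 0.80, 1.00)),
    PO = list(y = -0.70, labels = c("PO7", "PO3", "POz", "PO4", "PO8"),
              lat = c(-0.60, -0.30, 0, 0.30, 0.60)),
    O  = list(y = -0.90, labels = c("O1", "Oz", "O2"), lat = c(-0.30, 0, 0.30)),
    Iz = list(y = -1.05, labels = "Iz", lat = 0)
  )
  mont <- do.call(rbind, lapply(rows, function(r) {
    # shrink lateral spread toward the vertex so labels stay on the head disc
    width <- sqrt(max(1e-6, 1.1^2 - r$y^2))
    data.frame(label = r$labels, x = r$lat * width, y = r$y,
               stringsAsFactors = FALSE)
  }))
  rownames(mont) <- NULL
  stopifnot(nrow(mont) == 64L)
  if (n_channels < 10L || n_channels > 64L)
    stop("n_channels must be between 10 and 64", call. = FALSE)
  if (n_channels == 64L) return(mont)
  priority <- c(mu_channels(), alpha_channels(), "Fp1", "Fp2")
  keep <- c(priority, setdiff(mont$label, priority))[seq_len(n_channels)]
  out <- mont[match(keep, mont$label), ]
  out <- out[order(match(out$label, mont$label)), ]
  rownames(out) <- NULL
  out
}

#' Analysis electrode clusters
#'
#' The central (mu rhythm) and occipital (alpha rhythm) electrode clusters
#' over which band power is averaged.
#'
#' @return Character vector of channel labels.
#' @export
mu_channels <- function() c("C3", "C1", "Cz", "C2", "C4")

#' @rdname mu_channels
#' @export
alpha_channels <- function() c("O1", "Oz", "O2")

#' Default cluster definition used by the ERD stage
#'
#' @return Named list mapping cluster name to channel labels.
#' @export
default_clusters <- function() {
  list(mu_central = mu_channels(), alpha_occipital = alpha_channels())
}
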