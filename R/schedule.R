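#' Build a randomized trial schedule
#'
#' Generates the per-participant trial sequence: within each block every
#' (character, emotion) pair appears exactly once in uniformly random order;
#' fixation durations are drawn uniformly from `fixation_range`; Go/No-Go
#' cues are balanced within block at `go_ratio` (ties broken toward Go).
#' Trial onsets (stimulus start) are accumulated from fixation, stimulus and
#' cue durations and expressed as 0-based sample indices at `cfg$fs`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the schedule is a deterministic function of
#'   (cfg, seed).
#' @return data.frame of class `trial_schedule`: `trial_index`,
#'   `onset_sample` (0-based), `onset_ms`, `fixation_ms`, `character_id`,
#'   `group`, `emotion`, `block`, `cue`.
#' @examples
#' sched <- build_schedule(sim_config(), seed = 1)
#' nrow(sched)  # 96
#' @export
build_schedule <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(as.integer(seed))
  cells <- expand.grid(character_id = cfg$characters$character_id,
                       emotion = cfg$emotions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_cell <- nrow(cells)
  blocks <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    ord <- sample.int(n_cell)
    blk <- cells[ord, , drop = FALSE]
    blk$block <- b
    n_go <- ceiling(n_cell * cfg$go_ratio)  # ties toward go
    cue <- sample(c(rep("go", n_go), rep("no_go", n_cell - n_go)))
    blk$cue <- cue
    blocks[[b]] <- blk
  }
  sched <- do.call(rbind, blocks)
  sched$fixation_ms <- stats::runif(nrow(sched), cfg$fixation_range[1],
                                    cfg$fixation_range[2])
  trial_len <- cfg$stimulus_dur + sum(cfg$cue_dur)
  onset_ms <- cumsum(sched$fixation_ms + c(0, rep(trial_len,
                                                  nrow(sched) - 1L)))
  sched$onset_ms <- onset_ms
  sched$onset_sample <- round(onset_ms * cfg$fs / 1000)
  sched$group <- cfg$characters$group[match(sched$character_id,
                                            cfg$characters$character_id)]
  sched$trial_index <- seq_len(nrow(sched))
  sched <- sched[, c("trial_index", "onset_sample", "onset_ms", "fixation_ms",
                     "character_id", "group", "emotion", "block", "cue")]
  rownames(sched) <- NULL
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}
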