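#' Simulate and analyze a full multi-participant study
#'
#' For each participant: build a randomized schedule, synthesize the raw
#' recording, run the preprocessing chain, compute per-trial cluster band
#' power, then screen and aggregate to condition-level ERD indices. All
#' randomness derives from `seed`, so identical inputs give identical
#' outputs.
#'
#' @param cfg A [sim_config()] (its `n_participants` is used).
#' @param seed Integer master seed.
#' @param preproc A [preproc_config()].
#' @param clusters,band,windows ERD-stage settings.
#' @param mad_k Scaled-MAD trial-screening threshold.
#' @return list: `erd` ([erd_index()] table over all participants),
#'   `mu_alpha` ([mu_alpha_table()]), `trial_power`, `ground_truth`,
#'   `schedules`, and `counts` (epochs rejected etc. per participant).
#' @export
run_study <- function(cfg, seed = 1L, preproc = preproc_config(),
                      clusters = default_clusters(), band = erd_band(),
                      windows = phase_windows(), mad_k = 3) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * cfg$n_participants)
  tp_all <- vector("list", cfg$n_participants)
  gt_all <- vector("list", cfg$n_participants)
  sch_all <- vector("list", cfg$n_participants)
  counts <- vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("p%02d", p)
    sched <- build_schedule(cfg, seed = seeds[2L * p - 1L])
    sim <- synthesize_recording(sched, cfg, seed = seeds[2L * p],
                                participant = pid)
    ep <- preprocess_recording(sim$recording, preproc)
    tp_all[[p]] <- trial_power(ep, clusters, band, windows, participant = pid)
    gt_all[[p]] <- sim$ground_truth
    sched$participant <- pid
    sch_all[[p]] <- sched
    counts[[p]] <- data.frame(
      participant = pid,
      channels_interpolated = length(ep$provenance$interpolated),
      epochs_rejected = nrow(ep$provenance$rejected),
      epochs_kept = dim(ep$data)[1],
      high_artifact = ep$provenance$high_artifact,
      stringsAsFactors = FALSE)
  }
  tp <- do.call(rbind, tp_all)
  erd <- erd_index(tp, mad_k = mad_k)
  list(erd = erd, mu_alpha = mu_alpha_table(erd), trial_power = tp,
       ground_truth = do.call(rbind, gt_all),
       schedules = do.call(rbind, sch_all),
       counts = do.call(rbind, counts))
}

#' Simulate a condition-level ERD table (no EEG rendering)
#'
#' Draws participant x character x emotion ERD outcomes directly from the
#' variance-component model the full pipeline produces: participant random
#' intercept + condition means + cell noise. Used for fast error-rate and
#' power studies of the inference layer.
#'
#' @param n_participants Number of participants (clusters).
#' @param effects Named vector of true condition means (log10 power-ratio
#'   units) per character group; defaults to an all-zero null.
#' @param sd_participant SD of the participant random intercept.
#' @param sd_cell Residual SD of one participant x character x emotion cell.
#' @param characters,emotions Design (defaults as in [sim_config()]).
#' @return data.frame: `participant`, `character_id`, `group`, `emotion`,
#'   `mu`.
#' @export
simulate_erd_table <- function(n_participants,
                               effects = c(in_party = 0, out_party = 0,
                                           non_politician = 0),
                               sd_participant = 0.08, sd_cell = 0.1,
                               characters = default_characters(),
                               emotions = c("neutral", "happy", "angry")) {
  cells <- expand.grid(character_id = characters$character_id,
                       emotion = emotions, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells$group <- characters$group[match(cells$character_id,
                                        characters$character_id)]
  out <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
    b <- stats::rnorm(1, 0, sd_participant)
    data.frame(participant = sprintf("p%03d", p), cells,
               mu = effects[cells$group] + b +
                 stats::rnorm(nrow(cells), 0, sd_cell),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Empirical power of the out-vs-in clustered contrast
#'
#' Sweeps participants x blocks x effect size and reports, per cell, the
#' empirical rejection rate of the out-party vs in-party contrast from the
#' CR1 clustered OLS at the given alpha. Simulation is at the condition-table
#' level ([simulate_erd_table()]); the per-cell residual SD shrinks with the
#' number of block repetitions as `sd_trial / sqrt(blocks)`.
#'
#' @param n_participants Vector of participant counts.
#' @param n_blocks Vector of block counts.
#' @param effect Vector of true out-vs-in differences (log10 units;
#'   negative = more ERD for out-party).
#' @param n_sims Simulations per cell.
#' @param alpha Test level.
#' @param sd_participant,sd_trial Variance components.
#' @param seed Integer seed.
#' @return data.frame: one row per cell with `power`.
#' @export
power_sim <- function(n_participants = c(24, 48), n_blocks = 4,
                      effect = c(-0.05, -0.1), n_sims = 200, alpha = 0.05,
                      sd_participant = 0.08, sd_trial = 0.2, seed = 1L) {
  set.seed(as.integer(seed))
  grid <- expand.grid(n_participants = n_participants, n_blocks = n_blocks,
                      effect = effect, KEEP.OUT.ATTRS = FALSE)
  grid$power <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sd_cell <- sd_trial / sqrt(grid$n_blocks[i])
    rej <- vapply(seq_len(n_sims), function(s) {
      d <- simulate_erd_table(grid$n_participants[i],
                              effects = c(in_party = 0,
                                          out_party = grid$effect[i],
                                          non_politician = 0),
                              sd_participant = sd_participant,
                              sd_cell = sd_cell)
      fit <- erd_ols(mu ~ group, d, cluster = "participant")
      erd_contrast(fit, "group", "out_party", "in_party")$p < alpha
    }, logical(1))
    grid$power[i] <- mean(rej)
  }
  grid
}

#' Read and write run configurations (YAML)
#'
#' A persisted configuration re-creates identical simulation and
#' preprocessing settings; together with the seed recorded in the manifest it
#' re-runs to identical outputs.
#'
#' @param cfg A [sim_config()].
#' @param preproc A [preproc_config()].
#' @param path File path.
#' @return `read_run_config()` returns `list(sim = sim_config, preproc =
#'   preproc_config)`.
#' @export
write_run_config <- function(cfg, preproc = preproc_config(), path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  x$characters <- as.list(x$characters)
  # named vectors must become maps, or YAML drops the names
  for (nm in c("attenuation", "osc_freq", "osc_amplitude"))
    x[[nm]] <- as.list(x[[nm]])
  obj <- list(sim = x, preproc = unclass(preproc))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.list(obj) || is.null(obj$sim))
    stop("config schema violation in '", path, "': missing 'sim' section",
         call. = FALSE)
  s <- obj$sim
  s$characters <- as.data.frame(s$characters, stringsAsFactors = FALSE)
  for (nm in c("fixation_range", "dynamic_window", "cue_dur", "attenuation",
               "osc_freq", "osc_amplitude", "emotions"))
    s[[nm]] <- unlist(s[[nm]])
  sim <- do.call(sim_config, s)
  pp <- if (is.null(obj$preproc)) preproc_config() else {
    p <- obj$preproc
    p$epoch_window <- unlist(p$epoch_window)
    do.call(preproc_config, p)
  }
  list(sim = sim, preproc = pp)
}

#' Run the full pipeline and write its artifacts
#'
#' Runs [run_study()] and writes the stage outputs to `out_dir` as CSV
#' (schedules, ground truth, per-trial power, ERD indices, mu-alpha table,
#' provenance counts, default model coefficient and contrast tables), plus
#' `config.yaml` and a `manifest.json` recording the seed, package version
#' and MD5 of every written file, enabling exact re-runs.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if absent).
#' @param preproc A [preproc_config()].
#' @return Invisibly, the [run_study()] result.
#' @export
run_pipeline <- function(cfg, seed = 1L, out_dir, preproc = preproc_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_study(cfg, seed = seed, preproc = preproc)
  wr <- function(d, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(d, f, row.names = FALSE)
    f
  }
  files <- c(wr(res$schedules, "schedule.csv"),
             wr(res$ground_truth, "ground_truth.csv"),
             wr(res$trial_power, "trial_power.csv"),
             wr(res$erd, "erd_index.csv"),
             wr(res$mu_alpha, "mu_alpha.csv"),
             wr(res$counts, "provenance_counts.csv"))
  if (length(unique(res$mu_alpha$participant)) >= 2) {
    fit <- erd_ols(mu ~ group, res$mu_alpha, cluster = "participant")
    s <- summary(fit)$coefficients
    files <- c(files, wr(data.frame(term = rownames(s), s,
                                    check.names = FALSE), "coefficients.csv"))
    cons <- list(c("out_party", "in_party"), c("out_party", "non_politician"),
                 c("in_party", "non_politician"))
    ct <- do.call(rbind, lapply(cons, function(lv) {
      co <- erd_contrast(fit, "group", lv[1], lv[2])
      data.frame(contrast = paste(lv[1], "-", lv[2]), beta = co$estimate,
                 se = co$se, t = co$t, df = co$df, p = co$p, d = co$d)
    }))
    files <- c(files, wr(ct, "contrasts.csv"))
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(cfg, preproc, cfg_path)
  files <- c(files, cfg_path)
  manifest <- list(package = "muerd",
                   version = as.character(utils::packageVersion("muerd")),
                   seed = as.integer(seed),
                   files = data.frame(name = basename(files),
                                      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands; `inst/cli/muerd.R` is a thin Rscript
#' wrapper around this function. Returns an exit status (0 on success)
#' instead of quitting, so it can also be driven in-process.
#'
#' Subcommands: `simulate` (schedule + ground-truth CSVs per participant),
#' `run-all` (full pipeline, see [run_pipeline()]), `preprocess`, `erd`
#' (operate on a saved recording), `stats` (model a mu-alpha CSV table),
#' `power-sim`. Common flags: `--config <yaml>`, `--seed <int>`,
#' `--out <dir>`; `stats` takes `--table <csv>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: muerd <simulate|preprocess|erd|stats|",
                            "run-all|power-sim> [--config f] [--seed n] ",
                            "[--out dir] [--table f] [--in f]", call. = FALSE)
    cmd <- args[1]
    opts <- parse_cli_flags(args[-1])
    seed <- as.integer(opts$seed %||% 1L)
    out <- opts$out %||% "muerd_out"
    cfgs <- if (!is.null(opts$config)) {
      if (!file.exists(opts$config))
        stop("missing input: config file '", opts$config, "' does not exist",
             call. = FALSE)
      read_run_config(opts$config)
    } else list(sim = sim_config(), preproc = preproc_config())
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    switch(cmd,
      "simulate" = cli_simulate(cfgs$sim, seed, out),
      "preprocess" = cli_preprocess(cfgs$preproc, opts, out),
      "erd" = cli_erd(opts, out),
      "stats" = cli_stats(opts, out),
      "run-all" = run_pipeline(cfgs$sim, seed, out, cfgs$preproc),
      "power-sim" = utils::write.csv(power_sim(seed = seed),
                                     file.path(out, "power.csv"),
                                     row.names = FALSE),
      stop("unknown subcommand '", cmd, "'", call. = FALSE))
    0L
  }, error = function(e) {
    message("muerd error: ", conditionMessage(e))
    1L
  })
  status
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument '", args[i], "'", call. = FALSE)
    key <- substring(args[i], 3)
    if (i == length(args)) stop("flag --", key, " needs a value",
                                call. = FALSE)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

cli_simulate <- function(cfg, seed, out) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * cfg$n_participants)
  gt <- list(); sch <- list()
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("p%02d", p)
    s <- build_schedule(cfg, seeds[2L * p - 1L])
    sim <- synthesize_recording(s, cfg, seeds[2L * p], participant = pid)
    saveRDS(sim$recording, file.path(out, paste0("raw_", pid, ".rds")))
    s$participant <- pid
    utils::write.csv(s, file.path(out, paste0("schedule_", pid, ".csv")),
                     row.names = FALSE)
    gt[[p]] <- sim$ground_truth
  }
  utils::write.csv(do.call(rbind, gt), file.path(out, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

cli_preprocess <- function(preproc, opts, out) {
  f <- opts[["in"]] %||% stop("missing input: --in <raw .rds> required",
                              call. = FALSE)
  if (!file.exists(f)) stop("missing input: file '", f, "' does not exist",
                            call. = FALSE)
  ep <- preprocess_recording(readRDS(f), preproc)
  saveRDS(ep, file.path(out, "epochs.rds"))
  utils::write.csv(ep$provenance$rejected,
                   file.path(out, "rejection_log.csv"), row.names = FALSE)
  invisible(NULL)
}

cli_erd <- function(opts, out) {
  f <- opts[["in"]] %||% stop("missing input: --in <epochs .rds> required",
                              call. = FALSE)
  if (!file.exists(f)) stop("missing input: file '", f, "' does not exist",
                            call. = FALSE)
  tp <- trial_power(readRDS(f))
  erd <- erd_index(tp)
  utils::write.csv(tp, file.path(out, "trial_power.csv"), row.names = FALSE)
  utils::write.csv(erd, file.path(out, "erd_index.csv"), row.names = FALSE)
  invisible(NULL)
}

cli_stats <- function(opts, out) {
  f <- opts$table %||% stop("missing input: --table <mu_alpha csv> required",
                            call. = FALSE)
  if (!file.exists(f)) stop("missing input: file '", f, "' does not exist",
                            call. = FALSE)
  d <- utils::read.csv(f, stringsAsFactors = FALSE)
  need <- c("participant", "group", "emotion", "mu")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("validation error: table '", f, "' lacks column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  fit <- erd_ols(mu ~ group, d, cluster = "participant")
  s <- summary(fit)$coefficients
  utils::write.csv(data.frame(term = rownames(s), s, check.names = FALSE),
                   file.path(out, "coefficients.csv"), row.names = FALSE)
  invisible(NULL)
}
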