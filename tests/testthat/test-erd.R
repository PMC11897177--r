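test_that("phase windows cut the documented sample counts", {
  ep <- matrix(rnorm(8 * 1500), 8, 1500)
  segs <- extract_phase_windows(ep, fs = 250)
  expect_equal(ncol(segs$static), 275)    # 1100 ms at 250 Hz
  expect_equal(ncol(segs$dynamic), 513)   # 2050 ms, floor rule
  expect_error(phase_windows(static = c(0, 100), dynamic = c(50, 150)),
               "disjoint")
  short <- matrix(rnorm(8 * 100), 8, 100)
  expect_error(extract_phase_windows(short, fs = 250), "outside")
})

test_that("band PSD integrates a sinusoid to A^2/2 and is window-comparable", {
  fs <- 250
  a <- 2
  x <- a * sin(2 * pi * 10 * seq_len(2500) / fs)
  # integrated band power = band average density x bandwidth
  expect_equal(band_psd(x, erd_band(), fs) * 5, a^2 / 2, tolerance = 0.05)
  # white noise: full-range integral approximates the variance (Parseval)
  set.seed(5)
  v <- replicate(300, {
    z <- rnorm(1000, sd = 2)
    band_psd(z, erd_band(1, 124), fs) * 123
  })
  expect_equal(mean(v), 4 * 123 / 125, tolerance = 0.05)
  # the 1100 ms and 2050 ms windows give comparable densities on noise
  set.seed(6)
  both <- replicate(300, {
    z <- rnorm(513)
    c(band_psd(z[1:275], erd_band(), fs), band_psd(z, erd_band(), fs))
  })
  expect_equal(mean(both[1, ]) / mean(both[2, ]), 1, tolerance = 0.1)
  expect_error(band_psd(rnorm(20), erd_band(), fs), "too short")
})

test_that("trial ratio is dynamic over static with corrupt-trial errors", {
  expect_equal(trial_ratio(0.25, 1.0), 0.25)
  expect_equal(trial_ratio(3.7, 3.7), 1.0)
  expect_error(trial_ratio(-1, 2), "corrupt")
  expect_error(trial_ratio(1, 0), "corrupt")
})

test_that("scaled-MAD screening matches the hand computation", {
  x <- c(0.9, 1.0, 1.1, 1.0, 5.0)
  # median 1.0, scaled MAD = 1.4826 * 0.1, threshold 3 * 0.14826
  expect_equal(mad(x), 1.4826 * 0.1)
  expect_identical(mad_filter(x), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(mad_filter(rep(2.3, 10))))       # degenerate MAD
  expect_true(all(mad_filter(c(x, 100), k = Inf))) # threshold dominates
  expect_warning(keep <- mad_filter(c(1, 2, 3)), "fewer than 4")
  expect_true(all(keep))
})

test_that("mad_filter is order-invariant and equals the single-pass definition", {
  set.seed(9)
  for (i in 1:20) {
    x <- rlnorm(50, 0, 0.4)
    keep <- mad_filter(x)
    brute <- abs(x - median(x)) <= 3 * 1.4826 * median(abs(x - median(x)))
    expect_identical(keep, brute)
    p <- sample.int(50)
    expect_identical(mad_filter(x[p]), keep[p])
  }
})

test_that("condition aggregation is mean-then-log with cell bookkeeping", {
  tp <- data.frame(
    participant = "p01", trial_index = 1:8,
    character_id = rep(c("in1", "out1"), each = 4),
    group = rep(c("in_party", "out_party"), each = 4),
    emotion = "happy", block = rep(1:4, 2), cue = "go",
    cluster = "mu_central",
    psd_static = 1, psd_dynamic = 1,
    ratio = c(rep(0.25, 4), 0.1, 1.0, 0.1, 1.0),
    log_psd_static = 0, log_psd_dynamic = 0,
    kept = TRUE, stringsAsFactors = FALSE)
  erd <- erd_index(tp, mad_k = Inf)
  expect_equal(erd$value[erd$character_id == "in1"], log10(0.25))
  # mean-then-log, not log-then-mean: log10(mean(0.1,1,0.1,1)) = log10(0.55)
  expect_equal(erd$value[erd$character_id == "out1"], log10(0.55))
  expect_equal(erd$n_trials_kept, c(4L, 4L))
  # all-ones ratios give exactly 0
  tp$ratio <- 1
  expect_equal(erd_index(tp, mad_k = Inf)$value, c(0, 0))
})

test_that("screening is applied within participant x cluster", {
  tp <- expand.grid(block = 1:4, character_id = c("c1", "c2", "c3"),
                    participant = c("p01", "p02"),
                    cluster = "mu_central", stringsAsFactors = FALSE)
  tp$group <- "in_party"; tp$emotion <- "neutral"; tp$cue <- "go"
  tp$trial_index <- seq_len(nrow(tp))
  tp$psd_static <- 1; tp$psd_dynamic <- 1
  tp$log_psd_static <- 0; tp$log_psd_dynamic <- 0; tp$kept <- TRUE
  # p01 sits near 1.0 with one gross outlier; p02 sits near 3.0 entirely
  tp$ratio <- ifelse(tp$participant == "p01", 1, 3)
  tp$ratio[tp$participant == "p01"][1] <- 50
  tp$ratio <- tp$ratio + rep(seq(-0.05, 0.05, length.out = 12), 2)
  erd <- erd_index(tp)
  n1 <- sum(erd$n_trials_kept[erd$participant == "p01"])
  n2 <- sum(erd$n_trials_kept[erd$participant == "p02"])
  expect_equal(n1, 11L)  # outlier dropped within p01
  expect_equal(n2, 12L)  # p02's different level is not an outlier
})

test_that("the ERD table count matches the design (participants x 24 cells)", {
  tp <- expand.grid(block = 1:4,
                    character_id = default_characters()$character_id,
                    emotion = c("neutral", "happy", "angry"),
                    participant = sprintf("p%02d", 1:47),
                    cluster = c("mu_central", "alpha_occipital"),
                    stringsAsFactors = FALSE)
  tp$group <- default_characters()$group[
    match(tp$character_id, default_characters()$character_id)]
  tp$cue <- "go"; tp$trial_index <- seq_len(nrow(tp))
  tp$psd_static <- 1; tp$psd_dynamic <- 1
  set.seed(2); tp$ratio <- rlnorm(nrow(tp), 0, 0.1)
  tp$log_psd_static <- 0; tp$log_psd_dynamic <- 0; tp$kept <- TRUE
  erd <- erd_index(tp, mad_k = Inf)
  expect_equal(sum(erd$cluster == "mu_central"), 47 * 24)
  expect_equal(sum(erd$cluster == "alpha_occipital"), 47 * 24)
})

test_that("mu-alpha table aligns clusters and degenerates correctly", {
  erd <- expand.grid(character_id = c("c1", "c2"),
                     emotion = c("neutral", "happy"),
                     participant = c("p01", "p02"),
                     cluster = c("mu_central", "alpha_occipital"),
                     stringsAsFactors = FALSE)
  erd$group <- "in_party"
  set.seed(3)
  v <- rnorm(8)
  erd$value <- rep(v, 2)   # identical mu and alpha values
  erd$n_trials_kept <- 4L
  tab <- mu_alpha_table(erd)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$mu, tab$alpha)
  expect_equal(cor(tab$mu, tab$alpha), 1)
  expect_error(mu_alpha_table(erd[erd$cluster == "mu_central", ]),
               "alignment")
})

test_that("mu-alpha correlation rises with the spatial leakage width", {
  # full montage: on small montage subsets the average reference itself
  # couples the clusters and masks the kernel-width effect
  r_at <- function(width) {
    vals <- c()
    for (p in 1:6) {
      cfg <- sim_config(n_channels = 64, n_blocks = 1,
                        leakage_width = width,
                        attenuation = c(in_party = 0.85, out_party = 0.85,
                                        non_politician = 0.85))
      sched <- build_schedule(cfg, 100 + p)
      sim <- synthesize_recording(sched, cfg, 200 + p,
                                  participant = sprintf("p%02d", p))
      ep <- preprocess_recording(sim$recording)
      tp <- trial_power(ep, participant = sprintf("p%02d", p))
      vals <- rbind(vals, mu_alpha_table(erd_index(tp, mad_k = Inf)))
    }
    pearson_r(vals$mu, vals$alpha)$r
  }
  r <- c(r_at(0.15), r_at(0.25), r_at(0.35))
  # near-zero cross-cluster leakage: correlation near 0
  expect_lt(abs(r[1]), 0.25)
  # clear increase from minimal to moderate leakage
  expect_gt(r[3], r[1] + 0.1)
  expect_gt(r[3], 0.05)
  # the intermediate setting sits between the extremes (within noise)
  expect_gt(r[2], r[1] - 0.1)
  expect_lt(r[2], r[3] + 0.1)
})
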