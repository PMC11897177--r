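test_that("FFT resampling preserves length ratio, frequency content and event times", {
  fs <- 512
  t <- seq(0, 1, length.out = fs + 1)[-1]
  x <- matrix(sin(2 * pi * 10 * t), nrow = 1)
  x <- rbind(x, x)
  rec <- make_recording(x, fs, make_events(c(0L, 512L), fs))
  out <- resample_recording(rec, 250)
  expect_equal(ncol(out$data), 250)
  expect_equal(out$fs, 250)
  # dominant periodogram bin stays at 10 Hz
  spec <- Mod(fft(out$data[1, ]))[2:125]
  expect_equal(which.max(spec), 10)
  # event at 1 s maps to sample 250
  expect_equal(out$events$onset_sample, c(0, 250))
  expect_error(resample_recording(out, 512), "upsampling")
})

test_that("cached spectra and direct data give identical resampling", {
  cfg <- quick_cfg(n_blocks = 1, n_channels = 10)
  sched <- build_schedule(cfg, 1)
  rec <- synthesize_recording(sched, cfg, 2)$recording
  expect_false(is.null(attr(rec, "spectrum_cache")))
  rec_nocache <- rec
  attr(rec_nocache, "spectrum_cache") <- NULL
  a <- resample_recording(rec, 250)
  b <- resample_recording(rec_nocache, 250)
  expect_equal(a$data, b$data, tolerance = 1e-9)
})

test_that("band filter is zero-phase with the designed stop-band attenuation", {
  fs <- 250
  n <- 5000
  t <- seq_len(n) / fs
  mk <- function(f) make_recording(matrix(sin(2 * pi * f * t), 1), fs)
  amp <- function(rec) sqrt(2) * sd(rec$data[1, 1000:4000])
  # 10 Hz passband amplitude preserved within 5%
  expect_equal(amp(filter_band(mk(10), 0.1, 40)), 1, tolerance = 0.05)
  # 50 Hz amplitude reduced by at least 90%
  expect_lt(amp(filter_band(mk(50), 0.1, 40)), 0.1)
  # impulse response is symmetric about the impulse (zero phase)
  imp <- matrix(0, 1, n); imp[1, n / 2] <- 1
  h <- filter_band(make_recording(imp, fs), 0.1, 40)$data[1, ]
  expect_equal(which.max(h), n / 2)              # peak at lag 0
  expect_equal(h[n / 2 + 1:40], h[n / 2 - 1:40], tolerance = 1e-8)
  expect_error(filter_band(mk(10), 30, 20), "invalid filter")
  expect_error(filter_band(mk(10), 0.1, 200), "invalid filter")
})

test_that("kurtosis screening flags exactly the spiky channel", {
  set.seed(11)
  n <- 30000
  data <- matrix(rnorm(16 * n, sd = 10), nrow = 16)
  spikes <- sample.int(n, 25)
  data[5, spikes] <- 500
  rec <- make_recording(data, 250)
  expect_equal(detect_bad_channels(rec, z = 5), montage_64()$label[5])
  # direct kurtosis confirms the construction
  k <- apply(data, 1, e1071::kurtosis)
  expect_true(which.max(k) == 5 && k[5] > 50)
  # homogeneous channels: nothing flagged; infinite threshold: nothing
  clean <- make_recording(matrix(rnorm(16 * n), nrow = 16), 250)
  expect_identical(detect_bad_channels(clean, 5), character(0))
  expect_identical(detect_bad_channels(rec, Inf), character(0))
  expect_error(detect_bad_channels(make_recording(data[1:4, ], 250)),
               "insufficient channels")
})

test_that("rhythm-dominated (platykurtic) channels are never flagged as bad", {
  cfg <- quick_cfg(n_blocks = 1)
  sched <- build_schedule(cfg, 2)
  rec <- synthesize_recording(sched, cfg, 3)$recording
  expect_identical(detect_bad_channels(rec, 5), character(0))
})

test_that("bad-channel interpolation is an inverse-distance neighbor mean", {
  n <- 1000
  s <- sin(2 * pi * 7 * seq_len(n) / 250)
  # all channels carry the same signal -> interpolation reproduces it
  data <- matrix(rep(s, each = 16), nrow = 16)
  rec <- make_recording(data, 250)
  lab <- rec$channels$label[3]
  out <- interpolate_bad(rec, lab)
  expect_equal(out$data[3, ], s, tolerance = 1e-10)
  # empty bad list is the identity
  expect_identical(interpolate_bad(rec, character(0)), rec)
  # antisymmetric neighbors cancel: put +/-s on the 4 nearest of Cz
  mont <- montage_64()
  cz <- match("Cz", mont$label)
  rec2 <- make_recording(matrix(0, 64, n), 250)
  d <- sqrt((mont$x - mont$x[cz])^2 + (mont$y - mont$y[cz])^2)
  near <- setdiff(order(d), cz)[1:4]
  rec2$data[near[1], ] <- s;  rec2$data[near[2], ] <- -s
  rec2$data[near[3], ] <- s;  rec2$data[near[4], ] <- -s
  out2 <- interpolate_bad(rec2, "Cz")
  expect_lt(max(abs(out2$data[cz, ])), 1e-8)
  expect_error(interpolate_bad(rec, rec$channels$label[1:14]),
               "unrecoverable")
})

test_that("epoching is trial-locked with the documented sample arithmetic", {
  cfg <- quick_cfg(n_blocks = 4, noise_sd = 1,
                   osc_amplitude = c(mu = 1, alpha = 1))
  sched <- build_schedule(cfg, 1)
  rec <- synthesize_recording(sched, cfg, 2)$recording
  rec <- resample_recording(rec, 250)
  ep <- epoch_recording(rec, c(0, 6000))
  expect_equal(dim(ep$data)[1], 96)
  expect_equal(dim(ep$data)[3], 1500)  # 6 s x 250 Hz
  expect_equal(ep$events$trial_index, sched$trial_index)
  # recording cut before the last trial ends -> that trial dropped + warning
  cut <- rec
  cut$data <- cut$data[, seq_len(max(cut$events$onset_sample) + 100)]
  expect_warning(ep95 <- epoch_recording(cut, c(0, 6000)), "dropped")
  expect_equal(dim(ep95$data)[1], 95)
})

test_that("robust-z epoch rejection removes exactly the transient epochs", {
  set.seed(21)
  n_ep <- 96; n_ch <- 10; n_s <- 500
  data <- array(rnorm(n_ep * n_ch * n_s, sd = 10), c(n_ep, n_ch, n_s))
  bad <- c(7, 20, 41, 60, 88)
  for (j in bad) data[j, 3, 250] <- 500
  ep <- make_epochs(data, 250)
  out <- reject_epochs(ep, z = 5, max_fraction = 0.3)
  expect_equal(sort(out$provenance$rejected$trial_index), bad)
  expect_equal(dim(out$data)[1], n_ep - 5)
  # single-pass hand computation agrees on the first pass
  peaks <- apply(abs(data), 1, max)
  thr <- median(peaks) + 5 * mad(peaks)
  expect_equal(sort(which(peaks > thr)), bad)
  # idempotence: re-screening the survivors rejects nothing
  out2 <- reject_epochs(out, z = 5, max_fraction = 0.3)
  expect_equal(dim(out2$data)[1], dim(out$data)[1])
  # clean data: no rejections; identical epochs: scaled-MAD 0 keeps all
  clean <- make_epochs(array(rnorm(20 * 4 * 100), c(20, 4, 100)), 250)
  expect_equal(nrow(reject_epochs(clean, 5, 0.3)$provenance$rejected), 0)
  same <- make_epochs(array(rep(rnorm(4 * 100), each = 20), c(20, 4, 100)),
                      250)
  expect_equal(nrow(reject_epochs(same, 5, 0.3)$provenance$rejected), 0)
})

test_that("rejection stops at max_fraction and flags a high-artifact dataset", {
  set.seed(22)
  data <- array(rnorm(20 * 4 * 100), c(20, 4, 100))
  for (j in 1:8) data[j, 1, 50] <- 1000 + j
  ep <- make_epochs(data, 250)
  expect_warning(out <- reject_epochs(ep, z = 5, max_fraction = 0.25),
                 "high-artifact")
  expect_equal(nrow(out$provenance$rejected), 5)   # floor(0.25 * 20)
  expect_true(out$provenance$high_artifact)
  # the worst epochs go first
  expect_equal(sort(out$provenance$rejected$trial_index), 4:8)
})

test_that("average referencing zeroes the channel mean and is idempotent", {
  set.seed(31)
  data <- array(rnorm(5 * 8 * 200), c(5, 8, 200))
  ep <- make_epochs(data, 250)
  out <- average_reference(ep)
  for (j in 1:5)
    expect_lt(max(abs(colMeans(out$data[j, , ]))), 1e-9)
  expect_equal(average_reference(out)$data, out$data, tolerance = 1e-12)
  # common-mode offset is removed entirely
  shifted <- ep
  shifted$data <- ep$data + 42
  expect_equal(average_reference(shifted)$data, out$data, tolerance = 1e-9)
  # two channels s and -s are already average-referenced
  s <- sin(seq_len(200) / 10)
  two <- make_epochs(array(c(rbind(s, -s)), c(1, 2, 200)), 250)
  expect_equal(average_reference(two)$data, two$data, tolerance = 1e-12)
  one <- make_epochs(array(rnorm(200), c(1, 1, 200)), 250)
  expect_error(average_reference(one), "single channel")
})

test_that("the full chain keeps metadata and provenance consistent", {
  cfg <- quick_cfg(n_blocks = 1)
  sched <- build_schedule(cfg, 5)
  rec <- synthesize_recording(sched, cfg, 6)$recording
  ep <- preprocess_recording(rec)
  expect_s3_class(ep, "eeg_epochs")
  expect_equal(ep$fs, 250)
  expect_equal(dim(ep$data)[1] + nrow(ep$provenance$rejected), 24)
  expect_true(all(ep$events$trial_index %in% sched$trial_index))
  # ICA hook is honored
  marked <- preprocess_recording(rec, ica = function(e) { e$ica_ran <- TRUE; e })
  expect_true(marked$ica_ran)
})
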