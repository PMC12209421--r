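test_that("common average reference removes the channel mean exactly", {
  rec <- eeg_recording(matrix(c(1, 3), 2, 1), 10, c("C3", "C4"))
  out <- car_reference(rec)
  expect_equal(as.vector(out$samples), c(-1, 1))

  same <- eeg_recording(matrix(5, 4, 10), 10, c("C3", "C4", "Cz", "Pz"))
  expect_true(all(car_reference(same)$samples == 0))

  set.seed(1)
  r <- eeg_recording(matrix(rnorm(8 * 1000), 8), 100,
                     c("C3", "C4", "Cz", "Pz", "F3", "F4", "O1", "O2"))
  out <- car_reference(r)
  expect_lt(max(abs(colMeans(out$samples))), 1e-9)
  # idempotent projection
  expect_equal(car_reference(out)$samples, out$samples, tolerance = 1e-12)

  one <- eeg_recording(matrix(1, 1, 5), 10, "C3",
                       positions = standard_montage("C3"))
  expect_error(car_reference(one), "2 channels")
})

test_that("polyphase resampling preserves passband tones and kills aliases", {
  fs <- 1024
  t <- (0:(fs * 10 - 1)) / fs
  x <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
  rec <- eeg_recording(x, fs, c("C3", "C4"))
  out <- resample_recording(rec, 100)
  expect_equal(out$fs, 100)
  expect_equal(ncol(out$samples), 1000)
  sp <- Mod(stats::fft(out$samples[1, ]))[1:500]
  expect_equal(which.max(sp) - 1, 100)     # 10 Hz bin of a 10-s record
  mid <- 200:800
  expect_equal(stats::sd(out$samples[1, mid]) / stats::sd(x[1, ]), 1,
               tolerance = 0.02)

  # identity when target_fs == fs
  expect_identical(resample_recording(rec, fs)$samples, rec$samples)

  # 45 Hz content must be suppressed below 1% RMS after 1024 -> 100
  x45 <- rbind(sin(2 * pi * 45 * t), cos(2 * pi * 45 * t))
  out45 <- resample_recording(eeg_recording(x45, fs, c("C3", "C4")), 100)
  expect_lt(stats::sd(out45$samples[1, mid]) / stats::sd(x45[1, ]), 0.01)

  expect_error(resample_recording(rec, 2048), "upsampling")
})

test_that("Butterworth band-pass attenuates stop band, passes pass band", {
  fs <- 100
  t <- (0:(fs * 10 - 1)) / fs
  mk <- function(f) eeg_recording(rbind(sin(2 * pi * f * t),
                                        cos(2 * pi * f * t)),
                                  fs, c("C3", "C4"))
  stop2 <- bandpass_filter(mk(2), 4, 40)
  expect_lt(mean(stop2$samples[1, 300:900]^2) / 0.5, 0.01)
  pass20 <- bandpass_filter(mk(20), 4, 40)
  amp <- max(abs(pass20$samples[1, 500:900]))
  expect_equal(amp, 1, tolerance = 0.05)
  expect_error(bandpass_filter(mk(2), 4, 60), "Nyquist")
})

test_that("chunked causal filtering with state equals whole-record filtering", {
  coef <- butter_design(100, 4, 40, 4)
  set.seed(2)
  x <- matrix(rnorm(8 * 1000), 8)
  whole <- iir_apply(coef, x)$y
  st <- NULL
  pieces <- NULL
  for (i in seq(1, 1000, by = 12)) {       # ~125 ms chunks at 100 Hz
    ch <- iir_apply(coef, x[, i:min(i + 11, 1000), drop = FALSE], st)
    st <- ch$state
    pieces <- cbind(pieces, ch$y)
  }
  expect_lt(max(abs(whole - pieces)), 1e-9)
})

test_that("epoching cuts half-open windows and validates bounds", {
  fs <- 100
  x <- matrix(rnorm(2 * fs * 40), 2)
  ev <- tibble::tibble(onset_s = c(3, 10, 17, 24, 31),
                       label = c("a", "b", "a", "b", "a"))
  rec <- eeg_recording(x, fs, c("C3", "C4"), events = ev)
  ts <- epoch_trials(rec, -2, 5)
  expect_equal(dim(ts$data), c(5, 2, 700))
  expect_equal(ts$t0, 2)
  expect_equal(ts$labels, ev$label)
  # sample-exact content of the first trial
  expect_equal(ts$data[1, , ], x[, 101:800])

  tiny <- epoch_trials(rec, 0, 0.01)
  expect_equal(dim(tiny$data)[3], 1)

  late <- eeg_recording(x, fs, c("C3", "C4"),
                        events = tibble::tibble(onset_s = 39, label = "a"))
  expect_error(epoch_trials(late, 0, 3), "trial 1")
})

test_that("sliding windows follow floor((len - window)/step) + 1", {
  fs <- 100
  mk <- function(sec) matrix(rnorm(2 * fs * sec), 2)
  expect_length(sliding_windows(mk(5), fs), 33)
  expect_length(sliding_windows(mk(3), fs), 17)
  w1 <- sliding_windows(mk(1), fs)
  expect_length(w1, 1)
  expect_equal(w1[[1]]$start_s, 0)
  expect_error(sliding_windows(mk(0.5), fs), "shorter")

  # coverage: last window end <= trial end < last window end + step
  w <- sliding_windows(mk(3), fs)
  last_end <- w[[length(w)]]$start_s + 1
  expect_lte(last_end, 3)
  expect_lt(3, last_end + 0.125)
})

test_that("z-scoring uses population SD and survives flat channels", {
  seg <- eeg_segment(matrix(c(1, 2, 3), 1, 3), 3)
  out <- zscore_segment(seg)
  expect_equal(as.vector(out$data), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_true(out$standardized)

  again <- zscore_segment(out)
  expect_equal(again$data, out$data, tolerance = 1e-12)

  flat <- eeg_segment(rbind(c(5, 5, 5), c(1, 2, 3)), 3)
  expect_warning(zf <- zscore_segment(flat), "flat channel")
  expect_equal(as.vector(zf$data[1, ]), c(0, 0, 0))
})

test_that("artifact-trial rejection thresholds the flattened-trial SD", {
  set.seed(3)
  n <- 12
  dat <- array(rnorm(n * 4 * 100, sd = 5), c(n, 4, 100))
  dat[c(4, 9), , ] <- rnorm(2 * 4 * 100, sd = 50)
  ts <- trial_set(dat, rep(c("thumb", "pinky"), 6), 100)
  out <- reject_trials(ts, 20)
  expect_equal(out$rejected, c(4, 9))
  expect_equal(n_trials(out$trials), 10)
  expect_equal(out$trials$labels, ts$labels[-c(4, 9)])

  expect_equal(length(reject_trials(ts, Inf)$rejected), 0)
  expect_warning(all_gone <- reject_trials(ts, 0), "all trials")
  expect_equal(n_trials(all_gone$trials), 0)

  # monotonicity: a higher threshold removes a subset
  r1 <- reject_trials(ts, 10)$rejected
  r2 <- reject_trials(ts, 30)$rejected
  expect_true(all(r2 %in% r1))
})

test_that("channel selection preserves group order and flags unknowns", {
  ts <- fix_trialset()
  full <- select_channels(ts, channel_group("all", ts$channel_names))
  expect_equal(full$data, ts$data)

  grp <- channel_group("knob", c("C3", "FC1", "CP1"))
  sub <- select_channels(ts, grp)
  expect_equal(dim(sub$data)[2], 3)
  expect_equal(sub$channel_names, c("C3", "FC1", "CP1"))

  expect_error(select_channels(ts, channel_group("bad", c("C3", "XX9"))),
               "XX9")
})
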