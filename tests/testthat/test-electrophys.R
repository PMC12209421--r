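test_that("Morlet band power concentrates spectrally and scales quadratically", {
  ts <- sine_trials(n = 2, freq = 10)
  p_alpha <- morlet_band_power(ts, c(8, 13), c(0.5, 3))
  p_beta <- morlet_band_power(ts, c(14, 30), c(0.5, 3))
  expect_gt(mean(p_alpha) / mean(p_beta), 10)

  zero <- sine_trials(n = 2, amp = 0)
  expect_equal(max(morlet_band_power(zero, c(8, 13), c(0.5, 3))), 0)

  ts2 <- sine_trials(n = 2, amp = 10)
  expect_equal(mean(morlet_band_power(ts2, c(8, 13), c(0.5, 3))) /
                 mean(p_alpha), 4, tolerance = 0.01)

  # sign invariance
  flipped <- ts
  flipped$data <- -flipped$data
  expect_equal(morlet_band_power(flipped, c(8, 13), c(0.5, 3)), p_alpha,
               tolerance = 1e-10)

  # calibration: amplitude-A sinusoid at its own frequency reads A^2/2
  one <- sine_trials(n = 1, amp = 2, freq = 10)
  p10 <- morlet_band_power(one, c(10, 10), c(0.5, 2.5))
  expect_equal(mean(p10), 2, tolerance = 0.05)

  expect_error(morlet_band_power(ts, c(8, 13), c(-5, 3)), "window")
})

test_that("ERD identities: equal power gives 0%, halved power gives -50%", {
  same <- sine_trials(task_scale = 1)
  em0 <- erd_map(same, band = c(8, 13))
  expect_lt(max(abs(em0$erd)), 3)

  half <- sine_trials(task_scale = sqrt(0.5))
  em50 <- erd_map(half, band = c(8, 13), task_window = c(0.5, 2.5))
  expect_equal(mean(em50$erd), -50, tolerance = 3)

  expect_error(erd_map(sine_trials(t0 = 0.5)), "pre-onset")
  zero <- sine_trials(amp = 0)
  expect_error(erd_map(zero), "zero baseline")
})

test_that("generator ERD at the peak channel matches the closed-form oracle", {
  cfg <- synth_config(trials_per_class = 25, snr = 4, rhythm_variability = 0,
                      seed = 11)
  rec <- generate_session(cfg)
  ts <- rec |> preprocess_erd() |> epoch_trials(-2, 3)
  em <- erd_map(reject_trials(ts)$trials)
  ex <- expected_erd(rec)
  for (i in seq_len(nrow(ex))) {
    meas <- em$erd[em$class == ex$class[i] & em$channel == ex$channel[i]]
    expect_lt(abs(meas - ex$erd_expected[i]), 5)
  }
})

test_that("Morlet ERD agrees with a band-pass + Hilbert-envelope oracle", {
  ts <- sine_trials(task_scale = sqrt(0.4), noise = 0.5)
  em <- erd_map(ts, band = c(8, 13), task_window = c(0.5, 2.5))

  # oracle: zero-phase 8-13 Hz band-pass, analytic-signal envelope power
  co <- butter_design(ts$fs, 8, 13, 4)
  env_power <- function(x, i0, i1) {
    y <- fingerbci:::filtfilt_mat(co, x)
    n <- length(y[1, ])
    H <- stats::fft(y[1, ])
    h <- rep(0, n); h[1] <- 1
    if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
    else h[2:((n + 1) / 2)] <- 2
    a <- stats::fft(H * h, inverse = TRUE) / n
    mean(Mod(a[i0:i1])^2) / 2
  }
  i_task <- round((0.5 + 2) * ts$fs):round((2.5 + 2) * ts$fs)
  i_base <- round((-1 + 2) * ts$fs + 1):round(2 * ts$fs)
  erds <- sapply(seq_len(n_trials(ts)), function(i) {
    x <- matrix(ts$data[i, 1, ], nrow = 1)
    pt <- env_power(x, min(i_task), max(i_task))
    pb <- env_power(x, min(i_base), max(i_base))
    c(pt, pb)
  })
  oracle <- 100 * (mean(erds[1, ]) / mean(erds[2, ]) - 1)
  meas <- mean(em$erd[em$channel == "C3"])
  expect_lt(abs(meas - oracle), 3)
})

test_that("MRCP waveforms are baseline-corrected and recover the template", {
  # baseline mean is zero after correction
  cfg0 <- synth_config(trials_per_class = 8, mrcp_amplitude = 0, seed = 12)
  mr0 <- mrcp_waveform(generate_session(cfg0), trial_s = 3)
  bl <- mr0 |>
    dplyr::filter(.data$time_s < 0) |>
    dplyr::group_by(.data$class, .data$channel) |>
    dplyr::summarise(m = mean(.data$amplitude), .groups = "drop")
  expect_lt(max(abs(bl$m)), 1e-9)
  # null generator: no consistent post-onset deflection at C3
  post <- mr0 |> dplyr::filter(.data$channel == "C3", .data$time_s > 0)
  expect_lt(max(abs(post$amplitude)), 5)

  # template recovery through CAR + 0.3-3 Hz: expected trough from the
  # analytic template, the known spatial gain and the filter's |H|^2
  cfgm <- synth_config(trials_per_class = 50, mrcp_amplitude = 8, seed = 12)
  recm <- generate_session(cfgm)
  gen <- attr(recm, "generator")
  c3 <- match("C3", recm$channel_names)
  gain <- gen$g_mrcp[c3] - mean(gen$g_mrcp)
  fs <- 100; nt <- 4096
  tt <- (0:(nt - 1)) / fs
  templ <- -8 * exp(-(tt - 0.4)^2 / (2 * 0.18^2)) * cos(2 * pi * 1.4 * (tt - 0.4))
  co <- butter_design(fs, 0.3, 3, 2)
  fgrid <- (0:(nt - 1)) * fs / nt
  f2 <- pmin(fgrid, fs - fgrid)
  Hf <- vapply(f2, function(ff) {
    zz <- exp(-2i * pi * ff / fs)
    abs(sum(co$b * zz^(0:(length(co$b) - 1))) /
          sum(co$a * zz^(0:(length(co$a) - 1))))^2
  }, 0)
  filt <- Re(stats::fft(stats::fft(templ) * Hf, inverse = TRUE) / nt)
  expected_trough <- min(filt) * gain

  mr <- mrcp_waveform(recm, trial_s = 3)
  ga <- mr |>
    dplyr::filter(.data$channel == "C3") |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  win <- ga$time_s > 0.1 & ga$time_s < 0.8
  trough <- min(ga$amplitude[win])
  latency <- ga$time_s[win][which.min(ga$amplitude[win])]
  expect_lt(abs(trough - expected_trough) / abs(expected_trough), 0.2)
  expect_lt(abs(latency - 0.4), 0.15)
})

test_that("topography peak distance is a symmetric point-to-point measure", {
  pos <- standard_montage(c("C3", "C4", "Cz"))
  mk <- function(erd) {
    structure(tibble::tibble(class = "x", channel = pos$channel, erd = erd),
              positions = pos, class = c("erd_map", "tbl_df", "tbl", "data.frame"))
  }
  a <- mk(c(-50, -10, -5))
  b <- mk(c(-4, -60, -3))
  expect_equal(topography_distance(a, a), 0)
  d_ab <- topography_distance(a, b)
  expect_equal(d_ab, topography_distance(b, a))
  expect_equal(d_ab, sqrt(sum((as.numeric(pos[1, 2:4]) -
                                 as.numeric(pos[2, 2:4]))^2)))
  bad <- mk(c(-1, -2, -3))
  bad$channel <- c("F3", "F4", "Fz")
  expect_error(topography_distance(a, bad), "montage")

  # generator ordering: distant fingers peak farther apart than adjacent ones
  cfg <- synth_config(class_set = c("thumb", "index", "middle", "pinky"),
                      trials_per_class = 8, snr = 3, rhythm_variability = 0,
                      seed = 4)
  rec <- generate_session(cfg)
  ts <- rec |> preprocess_erd() |> epoch_trials(-2, 3)
  em <- erd_map(ts)
  one <- function(cl) {
    m <- em[em$class == cl, ]
    attr(m, "positions") <- attr(em, "positions")
    m
  }
  d_tp <- topography_distance(one("thumb"), one("pinky"))
  d_im <- topography_distance(one("index"), one("middle"))
  expect_gt(d_tp, d_im)
})
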