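# Electrophysiological analyses: Morlet-wavelet band power, ERD
# topographies, movement-related cortical potentials, and topography peak
# distances.
#
# Morlet convention: complex wavelet g(t) * exp(i 2 pi f t) with Gaussian
# envelope of width sigma_t = n_cycles / (2 pi f), envelope normalized to
# unit sum, and power reported as 2*|x * w|^2 so that a pure sinusoid of
# amplitude A measured at its own frequency yields its band variance A^2/2.

.morlet_kernel <- function(f, fs, n_cycles = 7) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3.5 * sigma_t * fs)
  t <- (-half:half) / fs
  g <- exp(-t^2 / (2 * sigma_t^2))
  g <- g / sum(g)
  g * exp(2i * pi * f * t)
}

# complex Morlet transform of a channels x time matrix at one frequency
# (FFT convolution, same length, centered)
.morlet_transform <- function(x, f, fs, n_cycles = 7) {
  w <- .morlet_kernel(f, fs, n_cycles)
  nw <- length(w)
  T <- ncol(x)
  nfft <- stats::nextn(T + nw - 1, 2)
  wf <- stats::fft(c(w, rep(0, nfft - nw)))
  out <- matrix(0i, nrow(x), T)
  half <- (nw - 1) / 2
  for (c in seq_len(nrow(x))) {
    xf <- stats::fft(c(x[c, ], rep(0, nfft - T)))
    conv <- stats::fft(xf * wf, inverse = TRUE) / nfft
    out[c, ] <- conv[(half + 1):(half + T)]
  }
  out
}

#' Morlet-wavelet band power per trial and channel
#'
#' Average over a 1-Hz frequency grid across the band and over the time
#' window of `2 |W x|^2` (squared magnitude of the Morlet transform,
#' calibrated so a sinusoid of amplitude A gives A^2/2 at its frequency).
#'
#' @param ts a [trial_set()].
#' @param band `c(low, high)` in Hz.
#' @param window `c(start, end)` in seconds relative to trial onset; must
#'   lie within the epoch.
#' @param n_cycles wavelet cycles (default 7).
#' @return matrix trials x channels of mean power (>= 0).
#' @export
morlet_band_power <- function(ts, band, window, n_cycles = 7) {
  stopifnot(inherits(ts, "trial_set"))
  tlen <- dim(ts$data)[3]
  i0 <- round((window[1] + ts$t0) * ts$fs) + 1
  i1 <- round((window[2] + ts$t0) * ts$fs)
  if (i0 < 1 || i1 > tlen || i0 > i1)
    stop("window outside the epoch", call. = FALSE)
  freqs <- seq(ceiling(band[1]), floor(band[2]))
  nt <- n_trials(ts)
  C <- dim(ts$data)[2]
  pow <- matrix(0, nt, C)
  for (tr in seq_len(nt)) {
    x <- ts$data[tr, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = C)
    acc <- matrix(0, C, i1 - i0 + 1)
    for (f in freqs) {
      W <- .morlet_transform(x, f, ts$fs, n_cycles)
      acc <- acc + 2 * Mod(W[, i0:i1, drop = FALSE])^2
    }
    pow[tr, ] <- rowMeans(acc) / length(freqs)
  }
  colnames(pow) <- ts$channel_names
  pow
}

#' ERD topography per class
#'
#' Relative band-power change, `ERD = (P_task - Rbar) / Rbar * 100` percent,
#' where `Rbar` is the session-average baseline power per channel (mean over
#' all trials of the 1-s pre-onset window) and `P_task` the per-trial task
#' power; single-trial ERD values are averaged within each class.
#'
#' @param ts a [trial_set()] preprocessed for ERD analysis (see
#'   [preprocess_erd()]) with at least 1 s of pre-onset context.
#' @param band analysis band (Hz), e.g. `c(8, 13)` alpha or `c(13, 30)`
#'   beta.
#' @param task_window `c(start, end)` s relative to onset; default 0.5 s to
#'   the trial end.
#' @param baseline_window default `c(-1, 0)`.
#' @param n_cycles Morlet cycles.
#' @return An `erd_map`: tibble `class`, `channel`, `erd` (percent), with
#'   channel positions attached as attribute `"positions"`.
#' @export
erd_map <- function(ts, band = c(8, 13), task_window = NULL,
                    baseline_window = c(-1, 0), n_cycles = 7) {
  stopifnot(inherits(ts, "trial_set"))
  if (ts$t0 < 1) stop("need at least 1 s of pre-onset context",
                      call. = FALSE)
  trial_end <- dim(ts$data)[3] / ts$fs - ts$t0
  if (is.null(task_window)) task_window <- c(0.5, trial_end)
  p_task <- morlet_band_power(ts, band, task_window, n_cycles)
  p_base <- morlet_band_power(ts, band, baseline_window, n_cycles)
  rbar <- colMeans(p_base)
  if (any(rbar <= 0))
    stop("zero baseline power at channel ",
         paste(ts$channel_names[rbar <= 0], collapse = ", "), call. = FALSE)
  erd_trial <- 100 * sweep(sweep(p_task, 2, rbar), 2, rbar, "/")
  out <- purrr::map_dfr(ts$class_set, function(cl) {
    idx <- which(ts$labels == cl)
    tibble::tibble(class = cl, channel = ts$channel_names,
                   erd = colMeans(erd_trial[idx, , drop = FALSE]))
  })
  structure(out, positions = ts$positions, band = band,
            class = c("erd_map", class(out)))
}

#' Movement-related cortical potential waveforms
#'
#' Common average reference, resampling to 100 Hz, 0.3-3 Hz zero-phase
#' band-pass, epoching with 1 s of pre-onset context, baseline correction
#' by the pre-onset-second mean, and per-class averaging.
#'
#' @param rec the raw [eeg_recording()] (original sampling rate).
#' @param trial_s trial length (s); default from the median inter-event gap
#'   is not attempted — pass it explicitly for non-3-s designs.
#' @return An `mrcp_result`: tibble `class`, `channel`, `time_s`,
#'   `amplitude` (microvolts); baseline-window means are 0 per channel.
#' @export
mrcp_waveform <- function(rec, trial_s = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$events) == 0) stop("recording has no events", call. = FALSE)
  if (min(rec$events$onset_s) < 1)
    stop("need at least 1 s of pre-onset context", call. = FALSE)
  prep <- rec |>
    car_reference() |>
    resample_recording(100) |>
    bandpass_filter(0.3, 3, order = 2, mode = "zero-phase")
  ts <- epoch_trials(prep, -1, trial_s)
  nt <- n_trials(ts)
  base_idx <- seq_len(round(1 * ts$fs))
  for (i in seq_len(nt)) {
    bl <- rowMeans(ts$data[i, , base_idx])
    ts$data[i, , ] <- ts$data[i, , ] - bl
  }
  tt <- (seq_len(dim(ts$data)[3]) - 1) / ts$fs - 1
  out <- purrr::map_dfr(ts$class_set, function(cl) {
    idx <- which(ts$labels == cl)
    avg <- apply(ts$data[idx, , , drop = FALSE], c(2, 3), mean)
    tibble::tibble(class = cl,
                   channel = rep(ts$channel_names, each = length(tt)),
                   time_s = rep(tt, times = nrow(avg)),
                   amplitude = as.vector(t(avg)))
  })
  structure(out, positions = ts$positions,
            class = c("mrcp_result", class(out)))
}

#' Distance between ERD activation peaks
#'
#' Euclidean distance (mm) between the scalp positions of the channels with
#' the most negative ERD (maximum desynchronization) in two maps.
#'
#' @param map_a,map_b single-class `erd_map`s (or tibbles with `channel`,
#'   `erd`) on the same montage.
#' @param positions tibble `channel,x,y,z`; default taken from `map_a`.
#' @return distance in mm.
#' @export
topography_distance <- function(map_a, map_b, positions = NULL) {
  if (is.null(positions)) positions <- attr(map_a, "positions")
  if (is.null(positions)) stop("montage positions required", call. = FALSE)
  if (!identical(sort(unique(map_a$channel)), sort(unique(map_b$channel))))
    stop("maps are not on the same montage", call. = FALSE)
  peak <- function(m) m$channel[which.min(m$erd)]
  pa <- positions[match(peak(map_a), positions$channel), c("x", "y", "z")]
  pb <- positions[match(peak(map_b), positions$channel), c("x", "y", "z")]
  sqrt(sum((as.numeric(pa) - as.numeric(pb))^2))
}
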