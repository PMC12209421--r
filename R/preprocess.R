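# Preprocessing: common average reference, polyphase resampling, Butterworth
# filtering (causal and zero-phase), epoching, sliding windows, z-scoring,
# artifact-trial rejection and channel selection.
#
# The online chain is applied in the order CAR -> resample -> causal band-pass
# -> window -> z-score; the offline ERD chain is CAR -> resample -> 2-30 Hz
# zero-phase -> epoch -> 20 uV rejection.

#' Common average reference
#'
#' Subtracts, at every time point, the instantaneous mean over channels.
#'
#' @param rec an [eeg_recording()].
#' @return The re-referenced recording.
#' @export
car_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < 2)
    stop("common average reference needs at least 2 channels", call. = FALSE)
  rec$samples <- sweep(rec$samples, 2, colMeans(rec$samples))
  rec
}

# Kaiser-windowed lowpass FIR for polyphase resampling.
# cutoff/transition are in units of the upsampled Nyquist (0..1).
kaiser_lowpass <- function(cutoff, transition, atten_db = 60) {
  beta <- if (atten_db > 50) 0.1102 * (atten_db - 8.7)
          else 0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  ntaps <- ceiling((atten_db - 8) / (2.285 * pi * transition))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1        # odd: integer group delay
  n <- seq_len(ntaps) - 1 - (ntaps - 1) / 2
  h <- cutoff * ifelse(n == 0, 1, sin(pi * cutoff * n) / (pi * cutoff * n))
  w <- besselI(beta * sqrt(pmax(0, 1 - (2 * n / (ntaps - 1))^2)), 0) /
    besselI(beta, 0)
  h * w
}

#' Resample a recording (downsampling only)
#'
#' Rational-ratio polyphase FIR resampling with a Kaiser-windowed anti-alias
#' filter (60 dB design attenuation, passband edge at 80% of the new Nyquist).
#' Event onsets, stored in seconds, are unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs new sampling rate (Hz), `<= rec$fs`.
#' @return The resampled recording.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs)
    stop("upsampling is not supported (target_fs > fs)", call. = FALSE)
  if (target_fs == rec$fs) return(rec)
  fr <- .rational(target_fs / rec$fs)
  up <- fr[1]; down <- fr[2]
  # passband to 0.7x the new Nyquist, stopband from 0.9x (so content at and
  # above 0.9x the new Nyquist is attenuated by the full design attenuation)
  cutoff <- 0.8 / max(up, down)
  transition <- 0.2 / max(up, down)
  h <- kaiser_lowpass(cutoff, transition) * up
  n_out <- floor(ncol(rec$samples) * up / down)
  rec$samples <- upfirdn_cpp(rec$samples, h, up, down, n_out)
  rownames(rec$samples) <- rec$channel_names
  rec$fs <- target_fs
  rec
}

.rational <- function(x, max_den = 10000) {
  # continued-fraction rational approximation
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (r == a) break
    r <- 1 / (r - a)
  }
  c(as.integer(p1), as.integer(q1))
}

#' Butterworth band-pass design
#'
#' @param fs sampling rate (Hz).
#' @param low lower edge (Hz); 0 selects a low-pass.
#' @param high upper edge (Hz), `< fs/2`.
#' @param order filter order (per edge), default 4.
#' @return list with `b`, `a` coefficients (a\[1\] == 1).
#' @export
butter_design <- function(fs, low, high, order = 4) {
  if (high >= fs / 2)
    stop("upper band edge must be below the Nyquist frequency", call. = FALSE)
  if (low < 0 || low >= high) stop("need 0 <= low < high", call. = FALSE)
  flt <- if (low == 0) signal::butter(order, high / (fs / 2), type = "low")
         else signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  list(b = as.numeric(flt$b), a = as.numeric(flt$a))
}

#' Apply an IIR filter with explicit state (streaming-capable)
#'
#' Direct-form-II-transposed filtering along time of a channels x time
#' matrix.  Passing the returned state back in filters a stream chunk by
#' chunk with output identical to filtering the whole signal at once.
#'
#' @param coef list with `b`, `a` from [butter_design()].
#' @param x channels x time numeric matrix.
#' @param state previous state matrix or `NULL` for zero initial state.
#' @return list with `y` (filtered matrix) and `state`.
#' @export
iir_apply <- function(coef, x, state = NULL) {
  x <- as.matrix(x)
  ns <- max(length(coef$a), length(coef$b)) - 1
  if (is.null(state)) state <- matrix(0, nrow(x), ns)
  out <- iir_filter_cpp(coef$b, coef$a, x, state)
  list(y = out$y, state = out$zf)
}

# zero-phase (forward-backward) filtering with odd-reflection padding
filtfilt_mat <- function(coef, x) {
  x <- as.matrix(x)
  np <- min(ncol(x) - 1, 3 * (max(length(coef$a), length(coef$b)) - 1) * 3)
  pad_l <- 2 * x[, 1] - x[, seq(np + 1, 2, -1), drop = FALSE]
  pad_r <- 2 * x[, ncol(x)] - x[, seq(ncol(x) - 1, ncol(x) - np), drop = FALSE]
  xp <- cbind(pad_l, x, pad_r)
  y <- iir_apply(coef, xp)$y
  y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  y <- iir_apply(coef, y)$y
  y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  y[, (np + 1):(np + ncol(x)), drop = FALSE]
}

#' Band-pass filter a recording
#'
#' Butterworth band-pass of the stated order; `causal` (forward-only,
#' streaming) for the online path, `zero-phase` (forward-backward) for
#' offline analyses.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges (Hz); `low = 0` selects a low-pass.
#' @param order Butterworth order, default 4.
#' @param mode `"causal"` or `"zero-phase"`.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low, high, order = 4,
                            mode = c("causal", "zero-phase")) {
  stopifnot(inherits(rec, "eeg_recording"))
  mode <- match.arg(mode)
  coef <- butter_design(rec$fs, low, high, order)
  rec$samples <- if (mode == "causal") iir_apply(coef, rec$samples)$y
                 else filtfilt_mat(coef, rec$samples)
  rownames(rec$samples) <- rec$channel_names
  rec
}

#' Epoch a recording into trials
#'
#' Cuts the half-open window `[onset + tmin, onset + tmax)` around every
#' event.  Sample indices are `round(t * fs)`; trial onset maps to relative
#' time 0.
#'
#' @param rec an [eeg_recording()] with events.
#' @param tmin window start relative to onset (s), typically negative.
#' @param tmax window end relative to onset (s).
#' @return A [trial_set()] with `t0 = -tmin`.
#' @export
epoch_trials <- function(rec, tmin, tmax) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (tmin >= tmax) stop("tmin must be < tmax", call. = FALSE)
  if (nrow(rec$events) == 0) stop("recording has no events", call. = FALSE)
  nsamp <- round((tmax - tmin) * rec$fs)
  n_tot <- ncol(rec$samples)
  dat <- array(0, c(nrow(rec$events), nrow(rec$samples), nsamp))
  for (i in seq_len(nrow(rec$events))) {
    start <- round((rec$events$onset_s[i] + tmin) * rec$fs)
    if (start < 0 || start + nsamp > n_tot)
      stop(sprintf("trial %d window [%.3f, %.3f) s exceeds record bounds",
                   i, rec$events$onset_s[i] + tmin,
                   rec$events$onset_s[i] + tmax), call. = FALSE)
    dat[i, , ] <- rec$samples[, (start + 1):(start + nsamp)]
  }
  trial_set(dat, rec$events$label, rec$fs, t0 = -tmin,
            channel_names = rec$channel_names, positions = rec$positions)
}

#' Sliding analysis windows over one trial
#'
#' Windows `[k*step, k*step + window)` for `k = 0..K-1` with
#' `K = floor((len - window)/step) + 1`.
#'
#' @param trial channels x samples matrix (a single trial), or a
#'   [trial_set()] together with `trial_index`.
#' @param fs sampling rate (Hz); taken from the trial set when one is given.
#' @param window_s window length (s), default 1.
#' @param step_s step (s), default 0.125.
#' @param trial_index which trial to window when `trial` is a trial set.
#' @return list of [eeg_segment()]s with `start_s` set (relative to the start
#'   of the supplied data).
#' @export
sliding_windows <- function(trial, fs = NULL, window_s = 1, step_s = 0.125,
                            trial_index = 1) {
  if (inherits(trial, "trial_set")) {
    fs <- trial$fs
    trial <- trial$data[trial_index, , ]
  }
  trial <- as.matrix(trial)
  wlen <- round(window_s * fs)
  step <- step_s * fs                      # may be fractional (12.5 at 100 Hz)
  if (ncol(trial) < wlen)
    stop("trial shorter than the analysis window", call. = FALSE)
  K <- floor((ncol(trial) - wlen) / step + 1e-9) + 1
  lapply(seq_len(K) - 1, function(k) {
    s0 <- round(k * step)
    eeg_segment(trial[, (s0 + 1):(s0 + wlen), drop = FALSE],
                fs, start_s = s0 / fs)
  })
}

#' Z-score a segment channel-wise
#'
#' Centers and scales every channel to mean 0, population SD 1.  A flat
#' channel (zero SD) maps to zeros with a warning instead of failing, so a
#' dead electrode cannot halt the online loop.
#'
#' @param seg an [eeg_segment()].
#' @return The standardized segment (`standardized = TRUE`).
#' @export
zscore_segment <- function(seg) {
  stopifnot(inherits(seg, "eeg_segment"))
  m <- rowMeans(seg$data)
  s <- sqrt(rowMeans(seg$data^2) - m^2)
  flat <- s <= 0 | !is.finite(s)
  if (any(flat)) {
    warning("flat channel(s) ", paste(which(flat), collapse = ", "),
            " mapped to zeros in z-scoring", call. = FALSE)
    s[flat] <- 1
    seg$data[flat, ] <- m[flat]   # will become zeros after centering
  }
  seg$data <- (seg$data - m) / s
  seg$standardized <- TRUE
  seg
}

# z-score an array of segments (segments x channels x samples), vectorized
zscore_array <- function(x) {
  m <- apply(x, c(1, 2), mean)
  s <- sqrt(pmax(apply(x, c(1, 2), function(v) mean(v^2)) - m^2, 0))
  s[s <= 0] <- 1
  (x - as.vector(m)) / as.vector(s)
}

#' Reject high-amplitude artifact trials
#'
#' Removes every trial whose standard deviation over all channel-samples
#' (population SD of the flattened trial) exceeds the threshold.
#'
#' @param ts a [trial_set()] (expected already preprocessed, e.g. 2-30 Hz).
#' @param sd_threshold_uV rejection threshold in microvolts, default 20.
#' @return list with `trials` (surviving [trial_set()], order preserved) and
#'   `rejected` (indices of removed trials).
#' @export
reject_trials <- function(ts, sd_threshold_uV = 20) {
  stopifnot(inherits(ts, "trial_set"))
  n <- n_trials(ts)
  if (n == 0) stop("empty trial set", call. = FALSE)
  sds <- vapply(seq_len(n), function(i) {
    v <- as.vector(ts$data[i, , ])
    sqrt(mean(v^2) - mean(v)^2)
  }, 0)
  rejected <- which(sds > sd_threshold_uV)
  if (length(rejected) == n)
    warning("all trials rejected at threshold ", sd_threshold_uV, " uV",
            call. = FALSE)
  keep <- setdiff(seq_len(n), rejected)
  list(trials = ts_subset(ts, keep), rejected = rejected, sd = sds)
}

#' Restrict a trial set to a channel group
#'
#' @param ts a [trial_set()].
#' @param group a [channel_group()] (or character vector of channel names).
#' @return The reduced trial set, channels in group order.
#' @export
select_channels <- function(ts, group) {
  stopifnot(inherits(ts, "trial_set"))
  members <- if (inherits(group, "channel_group")) group$members else group
  idx <- match(members, ts$channel_names)
  if (anyNA(idx))
    stop("channel(s) not in montage: ",
         paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
  out <- ts
  out$data <- ts$data[, idx, , drop = FALSE]
  out$channel_names <- ts$channel_names[idx]
  if (!is.null(ts$positions)) out$positions <- ts$positions[idx, ]
  out
}

#' Online preprocessing chain
#'
#' CAR, polyphase resampling to `target_fs`, causal Butterworth band-pass —
#' the chain applied sample-stream-wise before windowing and z-scoring.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs decoding rate (Hz), default 100.
#' @param low,high band edges (Hz), default 4-40.
#' @param order Butterworth order, default 4.
#' @return The preprocessed recording.
#' @export
preprocess_online <- function(rec, target_fs = 100, low = 4, high = 40,
                              order = 4) {
  rec |>
    car_reference() |>
    resample_recording(target_fs) |>
    bandpass_filter(low, high, order, mode = "causal")
}

#' Offline ERD preprocessing chain
#'
#' CAR, resampling to 100 Hz, 2-30 Hz zero-phase band-pass; epoching and
#' 20 uV rejection are applied by the caller (see [erd_map()]).
#'
#' @param rec an [eeg_recording()].
#' @return The preprocessed recording.
#' @export
preprocess_erd <- function(rec) {
  rec |>
    car_reference() |>
    resample_recording(100) |>
    bandpass_filter(2, 30, 4, mode = "zero-phase")
}
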