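#' Continuous EEG recording container
#'
#' Bundles a channels-by-time matrix of scalp potentials (microvolts) with its
#' sampling rate, channel names, 3-D channel positions and an event table of
#' trial onsets.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one per row of `samples`.
#' @param positions tibble/data.frame with columns `channel`, `x`, `y`, `z`
#'   (mm), or `NULL` to look positions up from the bundled montages.
#' @param events tibble/data.frame with columns `onset_s` (seconds from
#'   recording start, strictly increasing) and `label` (finger class).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_names,
                          positions = NULL, events = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric", call. = FALSE)
  if (length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar",
                                       call. = FALSE)
  if (length(channel_names) != nrow(samples))
    stop("channel_names length (", length(channel_names),
         ") != number of channels (", nrow(samples), ")", call. = FALSE)
  if (is.null(positions)) positions <- montage_positions(channel_names)
  positions <- tibble::as_tibble(positions)
  if (!all(c("channel", "x", "y", "z") %in% names(positions)) ||
      nrow(positions) != nrow(samples))
    stop("positions must have columns channel,x,y,z with one row per channel",
         call. = FALSE)
  if (is.null(events))
    events <- tibble::tibble(onset_s = numeric(), label = character())
  events <- tibble::as_tibble(events)
  dur <- ncol(samples) / fs
  if (nrow(events) > 0) {
    if (any(diff(events$onset_s) <= 0))
      stop("event onsets must be strictly increasing", call. = FALSE)
    if (any(events$onset_s < 0) || any(events$onset_s >= dur))
      stop("event onsets must lie within the record duration", call. = FALSE)
  }
  rownames(samples) <- channel_names
  structure(list(samples = samples, fs = fs,
                 channel_names = as.character(channel_names),
                 positions = positions, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, nrow(x$events)))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$samples)

#' Epoched trial container
#'
#' Trials x channels x samples array with per-trial finger labels.  `t0` is
#' the amount of pre-onset context included (seconds, >= 0): sample index
#' `round(t0 * fs) + 1` is the trial onset.
#'
#' @param data numeric array, trials x channels x samples.
#' @param labels character/factor vector of finger classes, one per trial.
#' @param fs sampling rate (Hz).
#' @param t0 pre-onset context included (s).
#' @param class_set ordered class names; defaults to sorted unique labels.
#' @param channel_names,positions montage metadata (as in [eeg_recording()]).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, labels, fs, t0 = 0, class_set = NULL,
                      channel_names = NULL, positions = NULL) {
  stopifnot(length(dim(data)) == 3)
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1])
    stop("one label per trial required", call. = FALSE)
  if (is.null(class_set)) class_set <- sort(unique(labels))
  if (!all(labels %in% class_set))
    stop("labels outside class_set", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2]))
  if (t0 < 0) stop("t0 must be >= 0", call. = FALSE)
  structure(list(data = data, labels = labels, fs = fs, t0 = t0,
                 class_set = class_set,
                 channel_names = as.character(channel_names),
                 positions = positions),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              d[1], d[2], d[3], x$fs, x$t0))
  cat("  classes:", paste(sprintf("%s (%d)", x$class_set,
                                  tabulate(factor(x$labels, x$class_set),
                                           length(x$class_set))),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$data)

n_trials <- function(ts) dim(ts$data)[1]

# subset trials, preserving metadata
ts_subset <- function(ts, idx) {
  trial_set(ts$data[idx, , , drop = FALSE], ts$labels[idx], ts$fs, ts$t0,
            ts$class_set, ts$channel_names, ts$positions)
}

#' Single analysis window of one trial
#'
#' @param data channels x samples matrix (microvolts, or z-units once
#'   standardized).
#' @param fs sampling rate (Hz).
#' @param start_s window start relative to trial onset (s).
#' @param standardized has [zscore_segment()] been applied?
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, fs, start_s = 0, standardized = FALSE) {
  structure(list(data = as.matrix(data), fs = fs, start_s = start_s,
                 standardized = isTRUE(standardized)),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d x %d @ %g Hz, start %.3f s%s\n",
              nrow(x$data), ncol(x$data), x$fs, x$start_s,
              if (x$standardized) " (z-scored)" else ""))
  invisible(x)
}

#' Named channel subset
#'
#' @param name group label (e.g. "left-hand-knob").
#' @param members channel names in the group.
#' @return An object of class `channel_group`.
#' @export
channel_group <- function(name, members) {
  members <- as.character(members)
  if (length(members) == 0) stop("channel group must be non-empty",
                                 call. = FALSE)
  structure(list(name = name, members = members), class = "channel_group")
}
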