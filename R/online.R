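# Closed-loop session simulation: per-125-ms decoding, probability
# smoothing, the robotic-hand flexion-accumulation rule, and the
# base / fine-tuned two-half session protocol.

#' Online protocol parameters
#'
#' Defaults follow the online finger-control design: 3-s trials, feedback
#' from 1 s to 3 s, one decoder update every 125 ms (16 updates), the
#' winning finger flexing 0.1 rad per update, 2-s inter-trial interval.
#'
#' @param trial_s trial length (s).
#' @param feedback_start_s feedback onset relative to trial onset (s); the
#'   first decodable 1-s window ends exactly here.
#' @param feedback_dur_s feedback duration (s); the feedback interval is
#'   half-open, so no update fires at `feedback_start_s + feedback_dur_s`.
#' @param update_s decoder update interval (s).
#' @param flex_step_rad per-update flexion increment of the winning finger.
#' @param iti_s inter-trial interval (s).
#' @param smoothing apply the probability smoother?
#' @param alpha smoother history weight, in `[0, 1)`.
#' @param normalize_history keep the L1-normalized (instead of raw) smoothed
#'   vector as the recursion state.
#' @return An `online_protocol` list.
#' @export
online_protocol <- function(trial_s = 3, feedback_start_s = 1,
                            feedback_dur_s = 2, update_s = 0.125,
                            flex_step_rad = 0.1, iti_s = 2,
                            smoothing = FALSE, alpha = 0.75,
                            normalize_history = FALSE) {
  stopifnot(feedback_start_s + feedback_dur_s <= trial_s, update_s > 0)
  if (alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)", call. = FALSE)
  structure(list(trial_s = trial_s, feedback_start_s = feedback_start_s,
                 feedback_dur_s = feedback_dur_s, update_s = update_s,
                 flex_step_rad = flex_step_rad, iti_s = iti_s,
                 smoothing = isTRUE(smoothing), alpha = alpha,
                 normalize_history = isTRUE(normalize_history)),
            class = "online_protocol")
}

#' Initialize the probability smoother
#'
#' The accumulator `h` starts at the zero vector.
#'
#' @param alpha history weight, in `[0, 1)`.
#' @param n_classes number of classes.
#' @param normalize_history see [online_protocol()].
#' @return A `smoother_state`.
#' @export
smoother_state <- function(alpha, n_classes, normalize_history = FALSE) {
  if (alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)", call. = FALSE)
  structure(list(h = rep(0, n_classes), alpha = alpha,
                 normalize_history = isTRUE(normalize_history)),
            class = "smoother_state")
}

#' One smoothing step
#'
#' Weighted sum of current and historical probabilities:
#' `P' = alpha * h + P`, the accumulator keeps `P'` (pre-normalization, per
#' the literal recursion; set `normalize_history` for the post-normalization
#' variant), and the returned vector is `P'` scaled to sum 1.
#'
#' @param state a [smoother_state()].
#' @param P probability vector (non-negative, sums to 1).
#' @return list with `P_smoothed` and the updated `state`.
#' @export
smooth_step <- function(state, P) {
  stopifnot(inherits(state, "smoother_state"))
  if (any(P < -1e-12) || abs(sum(P) - 1) > 1e-6)
    stop("P must be a probability vector", call. = FALSE)
  Pp <- state$alpha * state$h + P
  P_sm <- Pp / sum(Pp)
  state$h <- if (state$normalize_history) P_sm else Pp
  list(P_smoothed = P_sm, state = state)
}

#' Advance the robotic hand
#'
#' The winning finger flexes all four joints together by one step; the rest
#' hold their angles.
#'
#' @param hand named numeric vector of per-finger flexion angles (rad).
#' @param winner finger name.
#' @param step_rad flexion increment (rad), default 0.1.
#' @return The updated hand vector.
#' @export
hand_update <- function(hand, winner, step_rad = 0.1) {
  if (!winner %in% names(hand))
    stop("unknown finger: ", winner, call. = FALSE)
  hand[winner] <- hand[winner] + step_rad
  hand
}

#' Trial-level prediction from the hand state
#'
#' The finger that flexed the most is the predicted class.  Exact ties are
#' broken by the larger total probability of the tied fingers over the
#' trace's controlling (smoothed when smoothing was active) outputs.
#'
#' @param hand named flexion-angle vector after the feedback period.
#' @param trace the trial's `probability_trace`.
#' @return predicted class name.
#' @export
trial_prediction <- function(hand, trace) {
  if (is.null(trace) || length(trace$winner) == 0)
    stop("empty probability trace", call. = FALSE)
  mx <- max(hand)
  tied <- names(hand)[hand >= mx - 1e-12]
  if (length(tied) == 1) return(tied)
  ctrl <- trace$controlling
  sums <- colSums(ctrl[, tied, drop = FALSE])
  tied[which.max(sums)]
}

# assemble a probability trace object
probability_trace <- function(time_s, raw, smoothed, winner, classes,
                              smoothing) {
  colnames(raw) <- classes
  colnames(smoothed) <- classes
  structure(list(time_s = time_s, raw = raw, smoothed = smoothed,
                 winner = winner, classes = classes,
                 controlling = if (smoothing) smoothed else raw,
                 smoothing = smoothing),
            class = "probability_trace")
}

#' @export
print.probability_trace <- function(x, ...) {
  cat(sprintf("<probability_trace> %d updates, classes: %s%s\n",
              length(x$time_s), paste(x$classes, collapse = ", "),
              if (x$smoothing) " (smoothed)" else ""))
  invisible(x)
}

#' Simulate the closed loop over one trial
#'
#' From `feedback_start_s`, every `update_s`: take the most recent 1-s
#' window of the causally preprocessed stream, z-score it, decode, smooth
#' (optionally), and flex the winning finger.  The number of updates is
#' `feedback_dur_s / update_s` (16 under the default protocol).
#'
#' @param model a trained `eegnet_model`.
#' @param trial_mat channels x samples matrix of the causally preprocessed
#'   trial, first column at trial onset (t = 0), covering at least
#'   `[0, feedback_start_s + feedback_dur_s)`.
#' @param fs sampling rate of `trial_mat` (the decoding rate).
#' @param protocol an [online_protocol()].
#' @return list: `trace` (a `probability_trace`), `hand` (final angles),
#'   `prediction` (trial-level class).
#' @export
simulate_trial <- function(model, trial_mat, fs, protocol = online_protocol()) {
  p <- protocol
  U <- round(p$feedback_dur_s / p$update_s)
  times <- p$feedback_start_s + (seq_len(U) - 1) * p$update_s
  wlen <- round(1 * fs)
  need <- round((times[U]) * fs)
  if (ncol(trial_mat) < need)
    stop(sprintf("stream underrun: trial supplies %.3f s but update at %.3f s needs a full window",
                 ncol(trial_mat) / fs, times[U]), call. = FALSE)
  # gather all windows; decoding is per-window, so batching changes nothing
  X <- array(0, c(nrow(trial_mat), wlen, U))
  for (u in seq_len(U)) {
    e <- round(times[u] * fs)
    X[, , u] <- trial_mat[, (e - wlen + 1):e]
  }
  X <- zscore_array_seg(X)
  raw <- predict_proba(model, X)
  classes <- colnames(raw) %||% model$classes
  hand <- stats::setNames(rep(0, length(classes)), classes)
  st <- smoother_state(p$alpha, length(classes), p$normalize_history)
  smoothed <- raw
  winner <- character(U)
  for (u in seq_len(U)) {
    if (p$smoothing) {
      out <- smooth_step(st, raw[u, ])
      smoothed[u, ] <- out$P_smoothed
      st <- out$state
    }
    pvec <- if (p$smoothing) smoothed[u, ] else raw[u, ]
    winner[u] <- classes[which.max(pvec)]   # ties: lowest class index
    hand <- hand_update(hand, winner[u], p$flex_step_rad)
  }
  trace <- probability_trace(times, raw, smoothed, winner, classes,
                             p$smoothing)
  list(trace = trace, hand = hand, prediction = trial_prediction(hand, trace))
}

# z-score a C x T x N array segment-wise (population SD, flat -> zeros)
zscore_array_seg <- function(x) {
  m <- colMeans(aperm(x, c(2, 1, 3)))
  s <- sqrt(pmax(colMeans(aperm(x^2, c(2, 1, 3))) - m^2, 0))
  s[s <= 0] <- 1
  sweep_segments(x, m, s)
}

#' Run a full closed-loop session
#'
#' First-half runs are decoded with the base model; the first-half trials
#' then fine-tune the base model; second-half runs are decoded with the
#' fine-tuned model.  Mirrors the two-half online session design.
#'
#' @param base_model trained `eegnet_model`.
#' @param session an [eeg_recording()] (raw, with events).
#' @param protocol an [online_protocol()].
#' @param n_runs number of runs the session's trials divide into (16).
#' @param finetune_after runs decoded by the base model before fine-tuning
#'   (8).
#' @param train_cfg [train_config()] for the fine-tuning stage.
#' @param finetune should the second half use a fine-tuned model at all?
#' @return list: `results` (tibble, one row per trial: run, half, label,
#'   prediction, label_shifts, all_hit, trace/hand list-columns),
#'   `model_finetuned`.
#' @export
run_session <- function(base_model, session, protocol = online_protocol(),
                        n_runs = 16, finetune_after = 8,
                        train_cfg = train_config(), finetune = TRUE) {
  stopifnot(inherits(base_model, "eegnet_model"),
            inherits(session, "eeg_recording"))
  nt <- nrow(session$events)
  if (nt %% n_runs != 0)
    stop("trials (", nt, ") do not divide into ", n_runs, " runs",
         call. = FALSE)
  per_run <- nt %/% n_runs
  run_of <- rep(seq_len(n_runs), each = per_run)
  prep <- preprocess_online(session)
  ts_all <- epoch_trials(prep, 0, protocol$trial_s)
  classes <- base_model$classes %||% sort(unique(session$events$label))
  first_idx <- which(run_of <= finetune_after)

  decode_half <- function(model, idx, half) {
    rows <- lapply(idx, function(i) {
      out <- simulate_trial(model, ts_all$data[i, , ], prep$fs, protocol)
      tibble::tibble(trial = i, run = run_of[i], half = half,
                     label = ts_all$labels[i], prediction = out$prediction,
                     label_shifts = label_shifts(out$trace),
                     all_hit = all(out$trace$winner == ts_all$labels[i]),
                     trace = list(out$trace), hand = list(out$hand))
    })
    dplyr::bind_rows(rows)
  }

  res1 <- decode_half(base_model, first_idx, "base")
  model2 <- base_model
  if (finetune && length(first_idx) > 0 && finetune_after < n_runs) {
    ts_first <- ts_subset(ts_all, first_idx)
    ts_first$class_set <- classes
    model2 <- finetune_eegnet(base_model, ts_first, train_cfg)
  }
  res2 <- if (finetune_after < n_runs)
    decode_half(model2, which(run_of > finetune_after), "finetuned")
  else NULL
  list(results = dplyr::bind_rows(res1, res2), model_finetuned = model2)
}
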