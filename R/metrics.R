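# Evaluation metrics: majority-vote accuracy, per-class precision/recall,
# label shifts, all-hit ratio, and offline replay of stored sessions under
# alternative models.

#' Majority vote over per-update winners
#'
#' Modal label; ties are broken by the highest summed probability when a
#' trace is supplied, else by the lowest class index (first occurrence in
#' `class_order`, or sorted order).
#'
#' @param winners character vector of per-update winning labels.
#' @param trace optional `probability_trace` for tie-breaking.
#' @param class_order optional explicit class order for index tie-breaks.
#' @return the winning label.
#' @export
majority_vote <- function(winners, trace = NULL, class_order = NULL) {
  if (length(winners) == 0) stop("empty winner sequence", call. = FALSE)
  if (is.null(class_order)) class_order <- sort(unique(winners))
  counts <- table(factor(winners, class_order))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  if (!is.null(trace)) {
    sums <- colSums(trace$controlling[, top, drop = FALSE])
    return(top[which.max(sums)])
  }
  top[1]
}

#' Majority-vote accuracy (percent)
#'
#' @param results tibble with columns `label` and `prediction` (one row per
#'   trial), e.g. from [run_session()].
#' @return percentage of trials whose prediction matches the label.
#' @export
accuracy_pct <- function(results) {
  if (nrow(results) == 0) stop("no trials", call. = FALSE)
  100 * mean(results$label == results$prediction)
}

#' Per-class precision and recall (percent)
#'
#' Precision of class c: correctly-classified instances of c over all
#' instances predicted c; recall: correct predictions over all instances
#' truly of c.  A class never predicted has undefined precision, reported
#' as `NA` (not 0).
#'
#' @param results tibble with `label`, `prediction`.
#' @param classes optional class order.
#' @return tibble `class`, `precision`, `recall`, `n`.
#' @export
precision_recall <- function(results, classes = NULL) {
  if (nrow(results) == 0) stop("no trials", call. = FALSE)
  if (is.null(classes))
    classes <- sort(unique(c(results$label, results$prediction)))
  purrr::map_dfr(classes, function(cl) {
    tp <- sum(results$label == cl & results$prediction == cl)
    fp <- sum(results$label != cl & results$prediction == cl)
    fn <- sum(results$label == cl & results$prediction != cl)
    tibble::tibble(
      class = cl,
      precision = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp),
      recall = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
      n = tp + fn)
  })
}

#' Label shifts within a trial
#'
#' Number of updates whose winner differs from the previous update's.
#'
#' @param x a `probability_trace`, or a character vector of winners.
#' @return integer count in `[0, updates - 1]`.
#' @export
label_shifts <- function(x) {
  winners <- if (inherits(x, "probability_trace")) x$winner else x
  if (length(winners) == 0) stop("empty trace", call. = FALSE)
  sum(winners[-1] != winners[-length(winners)])
}

#' All-hit ratio (percent)
#'
#' Percentage of trials in which every update's winner matched the true
#' label.
#'
#' @param results tibble with logical column `all_hit` (as produced by
#'   [run_session()]), or with `trace` list-column plus `label`.
#' @return percentage in `[0, 100]`.
#' @export
all_hit_ratio <- function(results) {
  if (nrow(results) == 0) stop("no trials", call. = FALSE)
  hit <- if ("all_hit" %in% names(results)) results$all_hit
  else mapply(function(tr, lb) all(tr$winner == lb),
              results$trace, results$label)
  100 * mean(hit)
}

#' Session-level metric report
#'
#' @param results per-trial tibble from [run_session()] (or any tibble with
#'   `label`, `prediction`, and optionally `label_shifts`, `all_hit`).
#' @return one-row tibble: majority-vote accuracy, mean label shifts,
#'   all-hit ratio, n_trials; per-class precision/recall nested in
#'   `per_class`.
#' @export
metric_report <- function(results) {
  tibble::tibble(
    accuracy = accuracy_pct(results),
    mean_label_shifts = if ("label_shifts" %in% names(results))
      mean(results$label_shifts) else NA_real_,
    all_hit_ratio = if ("all_hit" %in% names(results) ||
                        "trace" %in% names(results))
      all_hit_ratio(results) else NA_real_,
    n_trials = nrow(results),
    per_class = list(precision_recall(results)))
}

#' Replay a stored session offline under alternative models
#'
#' Feeds identical decoding windows (regenerated with the same 1-s / 125-ms
#' windowing from the raw session) to every model and reports per-model
#' majority-vote metrics.  Replaying the very model used online reproduces
#' the online predictions exactly.
#'
#' @param models named list of trained `eegnet_model`s.
#' @param session the raw [eeg_recording()].
#' @param protocol the [online_protocol()] used online.
#' @return tibble: one row per model with the [metric_report()] columns,
#'   plus a `results` list-column of per-trial tibbles.
#' @export
replay_offline <- function(models, session, protocol = online_protocol()) {
  stopifnot(is.list(models), length(models) > 0)
  if (is.null(names(models)))
    names(models) <- paste0("model", seq_along(models))
  prep <- preprocess_online(session)
  ts_all <- epoch_trials(prep, 0, protocol$trial_s)
  purrr::map_dfr(names(models), function(nm) {
    model <- models[[nm]]
    if (model$spec$C != dim(ts_all$data)[2])
      stop("model/channel mismatch for ", nm, call. = FALSE)
    rows <- lapply(seq_len(n_trials(ts_all)), function(i) {
      out <- simulate_trial(model, ts_all$data[i, , ], prep$fs, protocol)
      tibble::tibble(trial = i, label = ts_all$labels[i],
                     prediction = out$prediction,
                     label_shifts = label_shifts(out$trace),
                     all_hit = all(out$trace$winner == ts_all$labels[i]),
                     trace = list(out$trace))
    })
    res <- dplyr::bind_rows(rows)
    dplyr::bind_cols(tibble::tibble(model = nm), metric_report(res),
                     tibble::tibble(results = list(res)))
  })
}
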