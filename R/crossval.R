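# Cross-validated majority-vote evaluation of decoders.
#
# Folds are stratified at the TRIAL level before any windowing, so no
# segment of a held-out trial ever reaches training; per-trial predictions
# are the majority vote over that trial's window predictions.

#' Decoder specification for cross-validation
#'
#' @param type `"eegnet"`, `"fbcsp"`, or the test stubs `"oracle"`
#'   (always returns the true label) and `"uniform"` (uniform random).
#' @param ... passed to the underlying fitter: for `"eegnet"`,
#'   `spec_args` (list passed to [eegnet_spec()] on top of the data
#'   geometry) and `train_cfg` (a [train_config()]); for `"fbcsp"`,
#'   arguments of [fbcsp_fit()].
#' @return A `decoder_spec`.
#' @export
decoder_spec <- function(type = c("eegnet", "fbcsp", "oracle", "uniform"),
                         ...) {
  structure(list(type = match.arg(type), args = list(...)),
            class = "decoder_spec")
}

# fit `dec` on ts_train and return per-trial majority-vote predictions on
# ts_test (list: prediction, per-segment winners by trial)
.fit_predict_trials <- function(dec, ts_train, ts_test, fold_seed) {
  classes <- ts_train$class_set
  if (dec$type == "oracle") {
    return(list(prediction = ts_test$labels,
                winners = lapply(seq_len(n_trials(ts_test)),
                                 function(i) rep(ts_test$labels[i], 17))))
  }
  if (dec$type == "uniform") {
    winners <- with_seed(fold_seed, lapply(seq_len(n_trials(ts_test)),
      function(i) sample(classes, 17, replace = TRUE)))
    return(list(prediction = vapply(winners, majority_vote, ""),
                winners = winners))
  }
  if (dec$type == "eegnet") {
    spec_args <- dec$args$spec_args %||% list()
    cfg <- dec$args$train_cfg %||% train_config()
    cfg$seed <- cfg$seed + fold_seed
    wlen <- round((dec$args$window_s %||% 1) * ts_train$fs)
    spec <- do.call(eegnet_spec, c(list(
      n_channels = dim(ts_train$data)[2], n_samples = wlen,
      n_classes = length(classes)), spec_args))
    model <- with_seed(cfg$seed, build_eegnet(spec))
    model <- train_eegnet(model, ts_train, cfg)
    segs <- make_segments(ts_test)
    p <- predict_proba(model, segs$x)
    winner <- classes[max.col(p, ties.method = "first")]
    winners <- split(winner, segs$trial)
    return(list(prediction = vapply(winners, majority_vote, ""),
                winners = winners))
  }
  # fbcsp
  fit_args <- dec$args
  model <- do.call(fbcsp_fit, c(list(ts = ts_train), fit_args))
  pr <- predict(model, ts_test)
  winner <- classes[max.col(pr$proba, ties.method = "first")]
  winners <- split(winner, pr$trial)
  list(prediction = vapply(winners, majority_vote, ""), winners = winners)
}

#' Stratified k-fold cross-validation with per-trial majority vote
#'
#' @param dec a [decoder_spec()].
#' @param ts a [trial_set()] at the decoding rate.
#' @param k folds (default 5); every class needs at least `k` trials.
#' @param seed seed controlling the fold assignment (and stub randomness).
#' @return A `crossval_result`: tibble of per-fold accuracies (percent) with
#'   attributes `mean`, `sd`, and the per-trial predictions.
#' @export
crossval <- function(dec, ts, k = 5, seed = 1) {
  stopifnot(inherits(dec, "decoder_spec"), inherits(ts, "trial_set"))
  counts <- table(factor(ts$labels, ts$class_set))
  if (any(counts < k))
    stop("every class needs at least k = ", k, " trials (have ",
         paste(counts, collapse = ", "), ")", call. = FALSE)
  folds <- with_seed(seed, {
    f <- integer(n_trials(ts))
    for (cl in ts$class_set) {
      idx <- sample(which(ts$labels == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  per_trial <- vector("list", k)
  for (fold in seq_len(k)) {
    tr <- ts_subset(ts, which(folds != fold))
    te_idx <- which(folds == fold)
    te <- ts_subset(ts, te_idx)
    out <- .fit_predict_trials(dec, tr, te, fold_seed = seed * 1000L + fold)
    per_trial[[fold]] <- tibble::tibble(fold = fold, trial = te_idx,
                                        label = te$labels,
                                        prediction = unname(out$prediction))
  }
  per_trial <- dplyr::bind_rows(per_trial)
  folds_tbl <- per_trial |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy = 100 * mean(.data$label == .data$prediction),
                     .groups = "drop")
  structure(folds_tbl,
            mean_accuracy = mean(folds_tbl$accuracy),
            sd_accuracy = stats::sd(folds_tbl$accuracy),
            predictions = per_trial,
            decoder = dec$type,
            class = c("crossval_result", class(folds_tbl)))
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %s: %.2f%% +/- %.2f%% over %d folds\n",
              attr(x, "decoder"), attr(x, "mean_accuracy"),
              attr(x, "sd_accuracy"), nrow(x)))
  NextMethod()
}
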