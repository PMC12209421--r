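# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a convolutional decoder
#'
#' @param x a trained `eegnet_model`.
#' @param ... unused.
#' @return tibble with one row per epoch: losses, validation accuracy,
#'   learning rate.
#' @export
tidy.eegnet_model <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  tibble::as_tibble(x$history)
}

#' One-row model summary
#' @param x a trained `eegnet_model`.
#' @param ... unused.
#' @export
glance.eegnet_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    variant = x$spec$variant,
    n_params = x$n_params,
    n_channels = x$spec$C, n_samples = x$spec$T,
    n_classes = x$spec$Z,
    epochs_trained = if (is.null(h)) 0L else nrow(h),
    best_val_loss = if (is.null(h)) NA_real_ else min(h$val_loss),
    best_val_acc = if (is.null(h)) NA_real_ else max(h$val_acc))
}

#' Per-band CSP eigenvalue summary of an FBCSP model
#' @param x an `fbcsp_model`.
#' @param ... unused.
#' @export
tidy.fbcsp_model <- function(x, ...) {
  purrr::map_dfr(x$problems, function(pr) {
    purrr::map_dfr(seq_along(x$bands), function(bi) {
      tibble::tibble(class = pr$class,
                     band_low = x$bands[[bi]][1],
                     band_high = x$bands[[bi]][2],
                     filter = seq_along(attr(pr$W[[bi]], "lambda")),
                     lambda = attr(pr$W[[bi]], "lambda"))
    })
  })
}

#' @export
glance.fbcsp_model <- function(x, ...) {
  tibble::tibble(n_bands = length(x$bands), n_pairs = x$n_pairs,
                 n_classes = length(x$classes), fs = x$fs)
}

#' Per-fold accuracies of a cross-validation run
#' @param x a `crossval_result`.
#' @param ... unused.
#' @export
tidy.crossval_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.crossval_result <- function(x, ...) {
  tibble::tibble(decoder = attr(x, "decoder"),
                 mean_accuracy = attr(x, "mean_accuracy"),
                 sd_accuracy = attr(x, "sd_accuracy"),
                 k = nrow(x))
}

#' Flat-projection scalp topography of an ERD map
#'
#' Channels are projected to the plane (azimuthal view from above) and
#' colored by ERD; one facet per class.
#'
#' @param object an `erd_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.erd_map <- function(object, ...) {
  pos <- attr(object, "positions")
  df <- dplyr::left_join(object, pos, by = "channel")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$erd)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::scale_color_gradient2(low = "#2166ac", mid = "grey90",
                                   high = "#b2182b", midpoint = 0,
                                   name = "ERD (%)") +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "left-right (mm)", y = "posterior-anterior (mm)",
                  title = "ERD topography") +
    ggplot2::theme_minimal()
}

#' Raw and smoothed class probabilities over a trial
#'
#' @param object a `probability_trace`.
#' @param ... unused.
#' @return a ggplot of per-class probability against time, one line per
#'   class, solid = controlling output, dashed = raw when smoothing was on.
#' @export
autoplot.probability_trace <- function(object, ...) {
  mk <- function(m, kind) {
    tibble::tibble(time_s = rep(object$time_s, ncol(m)),
                   class = rep(colnames(m), each = nrow(m)),
                   p = as.vector(m), kind = kind)
  }
  df <- mk(object$raw, "raw")
  if (object$smoothing) df <- dplyr::bind_rows(df, mk(object$smoothed,
                                                      "smoothed"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$p,
                                   color = .data$class,
                                   linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1 / length(object$classes),
                        linetype = "dotted", color = "grey40") +
    ggplot2::labs(x = "time from trial onset (s)", y = "probability") +
    ggplot2::theme_minimal()
}

#' MRCP waveform at selected channels
#'
#' @param object an `mrcp_result`.
#' @param channels channels to show (default "C3" when present).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mrcp_result <- function(object, channels = NULL, ...) {
  if (is.null(channels))
    channels <- if ("C3" %in% object$channel) "C3"
                else object$channel[1]
  df <- dplyr::filter(object, .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$amplitude,
                                   color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time from onset (s)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}
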