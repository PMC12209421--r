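# Compact convolutional EEG decoder (EEGNet-8,2 family).
#
# The R layer owns the parameter store, initialization, the Adam training
# loop with early stopping and reduce-on-plateau, max-norm constraints and
# the fine-tuning freeze contract; the per-batch forward/backward lives in
# src/eegnet.cpp.  All randomness (init, shuffling, dropout) is drawn from
# the R RNG, so a seed fixes training bit-exactly.

#' Decoder architecture specification
#'
#' @param n_channels,n_samples,n_classes input geometry: C channels, T
#'   samples (1-s window at the decoding rate), Z classes.
#' @param F1 temporal filters (8).
#' @param D depth multiplier of the spatial depthwise convolution (2).
#' @param F2 separable-convolution filters; `F1 * D` for the standard
#'   variant.
#' @param temporal_kernel_len temporal kernel length in samples; default
#'   half the decoding rate (50 at 100 Hz).
#' @param sep_kernel_len separable (depthwise temporal) kernel length (16).
#' @param pool1,pool2 average-pooling widths (4, 8).
#' @param dropout_rate dropout probability (0.5).
#' @param variant `"standard"` or `"deep"`; the deep variant doubles the
#'   filter counts and appends `extra_separable_blocks` further separable
#'   convolution blocks before the flatten.
#' @param extra_separable_blocks extra blocks for the deep variant (2).
#' @return An `eegnet_spec` list.
#' @export
eegnet_spec <- function(n_channels, n_samples, n_classes,
                        F1 = 8, D = 2, F2 = F1 * D,
                        temporal_kernel_len = 50, sep_kernel_len = 16,
                        pool1 = 4, pool2 = 8, dropout_rate = 0.5,
                        variant = c("standard", "deep"),
                        extra_separable_blocks = 2) {
  variant <- match.arg(variant)
  if (variant == "deep") {
    F1 <- F1 * 2
    F2 <- F1 * D
  } else {
    extra_separable_blocks <- 0
    if (F2 != F1 * D)
      stop("standard variant requires F2 == F1 * D", call. = FALSE)
  }
  T1 <- n_samples %/% pool1
  T2 <- T1 %/% pool2
  if (T2 < 1)
    stop("n_samples too short for the pooling stack; need at least ",
         pool1 * pool2, " samples", call. = FALSE)
  structure(list(C = as.integer(n_channels), T = as.integer(n_samples),
                 Z = as.integer(n_classes), F1 = as.integer(F1),
                 D = as.integer(D), F2 = as.integer(F2),
                 L = as.integer(temporal_kernel_len),
                 Ls = as.integer(sep_kernel_len),
                 pool1 = as.integer(pool1), pool2 = as.integer(pool2),
                 nblocks = as.integer(1 + extra_separable_blocks),
                 dropout = dropout_rate, variant = variant),
            class = "eegnet_spec")
}

# trainable parameter count, computed layer by layer
count_params <- function(spec) {
  M2 <- spec$F1 * spec$D
  T1 <- spec$T %/% spec$pool1
  T2 <- T1 %/% spec$pool2
  n <- spec$L * spec$F1 + 2 * spec$F1            # temporal conv + BN
  n <- n + spec$C * M2 + 2 * M2                  # depthwise conv + BN
  Min <- M2
  for (k in seq_len(spec$nblocks)) {
    Lk <- if (k == 1) spec$Ls else min(spec$Ls, T2)
    n <- n + Lk * Min + spec$F2 * Min + 2 * spec$F2
    Min <- spec$F2
  }
  n + spec$Z * (spec$F2 * T2) + spec$Z           # dense
}

#' Build an untrained decoder
#'
#' Glorot-uniform convolution/dense weights, unit-gain batch-norm; the
#' construction consumes the R RNG, so wrap in `set.seed()` for a fixed
#' initialization.
#'
#' @param spec an [eegnet_spec()].
#' @return An `eegnet_model` (untrained).
#' @export
build_eegnet <- function(spec) {
  stopifnot(inherits(spec, "eegnet_spec"))
  M2 <- spec$F1 * spec$D
  T1 <- spec$T %/% spec$pool1
  T2 <- T1 %/% spec$pool2
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  par <- list(
    Wt = glorot(spec$L, spec$F1, spec$L, spec$L),
    g1 = rep(1, spec$F1), b1 = rep(0, spec$F1),
    m1 = rep(0, spec$F1), v1 = rep(1, spec$F1),
    Wdw = glorot(spec$C, M2, spec$C, spec$C),
    g2 = rep(1, M2), b2 = rep(0, M2),
    m2 = rep(0, M2), v2 = rep(1, M2))
  Min <- M2
  for (k in seq_len(spec$nblocks) - 1) {
    Lk <- if (k == 0) spec$Ls else min(spec$Ls, T2)
    par[[paste0("Wdep", k)]] <- glorot(Lk, Min, Lk, Lk)
    par[[paste0("Wpt", k)]] <- glorot(spec$F2, Min, Min, spec$F2)
    par[[paste0("g3", k)]] <- rep(1, spec$F2)
    par[[paste0("b3", k)]] <- rep(0, spec$F2)
    par[[paste0("m3", k)]] <- rep(0, spec$F2)
    par[[paste0("v3", k)]] <- rep(1, spec$F2)
    Min <- spec$F2
  }
  par$Wfc <- glorot(spec$Z, spec$F2 * T2, spec$F2 * T2, spec$Z)
  par$bfc <- rep(0, spec$Z)
  structure(list(spec = spec, par = par, classes = NULL,
                 n_params = count_params(spec), history = NULL),
            class = "eegnet_model")
}

#' @export
print.eegnet_model <- function(x, ...) {
  cat(sprintf("<eegnet_model> %s variant: C=%d T=%d Z=%d (%d trainable parameters)%s\n",
              x$spec$variant, x$spec$C, x$spec$T, x$spec$Z, x$n_params,
              if (is.null(x$history)) " [untrained]" else ""))
  invisible(x)
}

# parameter names excluded from gradient updates (BN running stats)
.running_names <- function(par) grep("^(m|v)", names(par), value = TRUE)

# names of the first-four-layer parameters frozen during fine-tuning:
# temporal conv + its BN, depthwise conv + its BN (running stats included)
.frozen_names <- c("Wt", "g1", "b1", "m1", "v1", "Wdw", "g2", "b2", "m2", "v2")

#' Training configuration
#'
#' @param max_epochs maximum training epochs (default 300).
#' @param patience early-stopping patience on validation loss (default 20);
#'   the best-validation weights are restored.
#' @param val_fraction stratified validation fraction (by trial), default 0.1.
#' @param batch_size minibatch size (64).
#' @param lr Adam learning rate (1e-3).
#' @param lr_patience,lr_factor reduce-on-plateau schedule (10, 0.5).
#' @param weight_decay decoupled L2 decay applied to convolution and dense
#'   weights (not batch-norm), default 1e-3; lets weights that carry no
#'   class information shrink away.
#' @param seed RNG seed fixing initialization, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 300, patience = 20, val_fraction = 0.1,
                         batch_size = 64, lr = 1e-3, lr_patience = 10,
                         lr_factor = 0.5, weight_decay = 1e-3, seed = 1) {
  stopifnot(max_epochs >= 1, val_fraction > 0, val_fraction < 1)
  structure(list(max_epochs = max_epochs, patience = patience,
                 val_fraction = val_fraction, batch_size = batch_size,
                 lr = lr, lr_patience = lr_patience, lr_factor = lr_factor,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

# Cut every trial into 1-s z-scored windows; returns x (C x T x Nseg),
# y (0-based class index), trial (parent trial index).
make_segments <- function(ts, window_s = 1, step_s = 0.125) {
  wlen <- round(window_s * ts$fs)
  step <- step_s * ts$fs                   # fractional steps allowed
  nt <- n_trials(ts)
  tlen <- dim(ts$data)[3]
  if (tlen < wlen) stop("trials shorter than the window", call. = FALSE)
  K <- floor((tlen - wlen) / step + 1e-9) + 1
  C <- dim(ts$data)[2]
  x <- array(0, c(C, wlen, nt * K))
  y <- integer(nt * K)
  trial <- integer(nt * K)
  i <- 0L
  for (tr in seq_len(nt)) {
    cls <- match(ts$labels[tr], ts$class_set) - 1L
    for (k in seq_len(K) - 1L) {
      i <- i + 1L
      s0 <- round(k * step)
      x[, , i] <- ts$data[tr, , (s0 + 1):(s0 + wlen)]
      y[i] <- cls
      trial[i] <- tr
    }
  }
  # channel-wise z-score each segment (population SD; flat channels -> 0)
  m <- colMeans(aperm(x, c(2, 1, 3)))                   # C x Nseg
  s <- sqrt(pmax(colMeans(aperm(x^2, c(2, 1, 3))) - m^2, 0))
  s[s <= 0] <- 1
  x <- sweep_segments(x, m, s)
  list(x = x, y = y, trial = trial, classes = ts$class_set)
}

sweep_segments <- function(x, m, s) {
  d <- dim(x)
  mm <- aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2))
  ss <- aperm(array(s, c(d[1], d[3], d[2])), c(1, 3, 2))
  (x - mm) / ss
}

.cpp_spec <- function(spec) spec[c("C", "T", "Z", "F1", "D", "F2", "L", "Ls",
                                   "pool1", "pool2", "nblocks")]

.apply_maxnorm <- function(par, spec, skip_dw = FALSE) {
  # depthwise spatial filters: L2 norm over channels <= 1 (skipped when the
  # spatial layer is frozen: renormalizing would perturb it by an ulp)
  if (!skip_dw) {
    nrm <- sqrt(colSums(par$Wdw^2))
    over <- nrm > 1
    if (any(over)) par$Wdw[, over] <- sweep(par$Wdw[, over, drop = FALSE],
                                            2, nrm[over], "/")
  }
  # dense rows: L2 norm <= 0.25
  nrm <- sqrt(rowSums(par$Wfc^2))
  over <- nrm > 0.25
  if (any(over)) par$Wfc[over, ] <- par$Wfc[over, , drop = FALSE] *
      (0.25 / nrm[over])
  par
}

# core SGD loop shared by training and fine-tuning
.fit_eegnet <- function(model, segs, cfg, freeze_front) {
  spec <- model$spec
  cspec <- .cpp_spec(spec)
  par <- model$par
  frozen <- if (freeze_front) .frozen_names else character()
  updatable <- setdiff(names(par), c(.running_names(par), frozen))

  with_seed(cfg$seed, {
    # stratified validation split at trial level
    trials <- unique(segs$trial)
    tr_lab <- segs$y[match(trials, segs$trial)]
    val_trials <- unlist(lapply(split(trials, tr_lab), function(tt) {
      nv <- max(1, round(length(tt) * cfg$val_fraction))
      sample(tt, nv)
    }))
    is_val <- segs$trial %in% val_trials
    if (all(is_val) || !any(is_val))
      stop("validation split failed: too few trials", call. = FALSE)
    Xtr <- segs$x[, , !is_val, drop = FALSE]
    ytr <- segs$y[!is_val]
    Xva <- segs$x[, , is_val, drop = FALSE]
    yva <- segs$y[is_val]
    if (length(unique(ytr)) < spec$Z)
      stop("a class is absent from the training split", call. = FALSE)

    adam_m <- lapply(par[updatable], function(p) p * 0)
    adam_v <- adam_m
    lr <- cfg$lr
    t_step <- 0
    best_val <- Inf; best_par <- par; wait <- 0; lr_wait <- 0
    hist <- list()
    n_tr <- length(ytr)
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample(n_tr)
      ep_loss <- 0; nb <- 0
      for (b0 in seq(1, n_tr, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, n_tr)]
        if (length(idx) < 2) next
        out <- eegnet_pass(par, cspec, Xtr[, , idx, drop = FALSE],
                           as.integer(ytr[idx]), TRUE, freeze_front,
                           spec$dropout)
        for (nm in names(out$running)) par[[nm]] <- out$running[[nm]]
        t_step <- t_step + 1
        wd_names <- grep("^(Wt|Wdw|Wdep|Wpt|Wfc)", updatable, value = TRUE)
        for (nm in updatable) {
          g <- out$grads[[nm]]
          adam_m[[nm]] <- 0.9 * adam_m[[nm]] + 0.1 * g
          adam_v[[nm]] <- 0.999 * adam_v[[nm]] + 0.001 * g^2
          mh <- adam_m[[nm]] / (1 - 0.9^t_step)
          vh <- adam_v[[nm]] / (1 - 0.999^t_step)
          par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
          if (nm %in% wd_names)
            par[[nm]] <- par[[nm]] * (1 - lr * cfg$weight_decay)
        }
        par <- .apply_maxnorm(par, spec, skip_dw = freeze_front)
        ep_loss <- ep_loss + out$loss; nb <- nb + 1
      }
      pv <- eegnet_forward_cpp(par, cspec, Xva)
      val_loss <- -mean(log(pmax(pv[cbind(yva + 1L, seq_along(yva))], 1e-12)))
      val_acc <- mean(max.col(t(pv)) - 1L == yva)
      hist[[ep]] <- c(epoch = ep, train_loss = ep_loss / max(nb, 1),
                      val_loss = val_loss, val_acc = val_acc, lr = lr)
      if (val_loss < best_val - 1e-5) {
        best_val <- val_loss; best_par <- par; wait <- 0; lr_wait <- 0
      } else {
        wait <- wait + 1; lr_wait <- lr_wait + 1
        if (lr_wait >= cfg$lr_patience) { lr <- lr * cfg$lr_factor; lr_wait <- 0 }
        if (wait >= cfg$patience) break
      }
    }
    model$par <- best_par
    model$classes <- segs$classes
    model$history <- dplyr::bind_rows(lapply(hist, as.list))
    model
  })
}

#' Train the decoder
#'
#' Consumes 1-s z-scored sliding windows of the trials (labels inherited
#' from the parent trial), with a stratified trial-level validation split,
#' Adam, early stopping restoring the best-validation weights, and a
#' reduce-on-plateau learning-rate schedule.  Deterministic given
#' `cfg$seed`.
#'
#' @param model an untrained or trained `eegnet_model`.
#' @param ts a [trial_set()] at the decoding rate (windows are cut here).
#' @param cfg a [train_config()].
#' @param window_s,step_s windowing of trials (1 s / 125 ms).
#' @return The trained model; per-epoch history in `$history`.
#' @export
train_eegnet <- function(model, ts, cfg = train_config(),
                         window_s = 1, step_s = 0.125) {
  stopifnot(inherits(model, "eegnet_model"), inherits(ts, "trial_set"))
  if (length(unique(ts$labels)) < 2)
    stop("need at least 2 classes to train", call. = FALSE)
  if (!all(ts$class_set %in% unique(ts$labels)))
    stop("class absent from training data: ",
         paste(setdiff(ts$class_set, unique(ts$labels)), collapse = ", "),
         call. = FALSE)
  segs <- make_segments(ts, window_s, step_s)
  model <- .fit_eegnet(model, segs, cfg, freeze_front = FALSE)
  model$channel_names <- ts$channel_names
  model
}

#' Fine-tune a trained decoder on same-day data
#'
#' Continues training with the parameters of the first four layers
#' (temporal convolution and its batch-norm, depthwise spatial convolution
#' and its batch-norm) frozen bit-exactly, including their running
#' statistics; the remaining layers adapt to the same-day distribution.
#'
#' @param model a trained `eegnet_model`.
#' @param ts same-day [trial_set()].
#' @param cfg a [train_config()].
#' @param window_s,step_s windowing of trials.
#' @return The fine-tuned model.
#' @export
finetune_eegnet <- function(model, ts, cfg = train_config(),
                            window_s = 1, step_s = 0.125) {
  stopifnot(inherits(model, "eegnet_model"))
  if (is.null(model$history))
    stop("fine-tuning requires a trained base model", call. = FALSE)
  if (!inherits(ts, "trial_set") || n_trials(ts) == 0)
    stop("fine-tuning set is empty", call. = FALSE)
  segs <- make_segments(ts, window_s, step_s)
  .fit_eegnet(model, segs, cfg, freeze_front = TRUE)
}

#' Class probabilities for segments
#'
#' @param model a trained `eegnet_model`.
#' @param x an [eeg_segment()] (standardized), or a C x T x N array of
#'   z-scored segments.
#' @return matrix N x Z of probabilities (rows sum to 1), columns named by
#'   class when known.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "eegnet_model"))
  if (inherits(x, "eeg_segment")) {
    if (!x$standardized)
      stop("segment must be z-scored before decoding", call. = FALSE)
    x <- array(x$data, c(dim(x$data), 1))
  }
  d <- dim(x)
  if (length(d) == 2) x <- array(x, c(d, 1))
  d <- dim(x)
  if (d[1] != model$spec$C || d[2] != model$spec$T)
    stop(sprintf("segment is %d x %d but the model expects %d x %d",
                 d[1], d[2], model$spec$C, model$spec$T), call. = FALSE)
  p <- t(eegnet_forward_cpp(model$par, .cpp_spec(model$spec), x))
  if (!is.null(model$classes)) colnames(p) <- model$classes
  p
}

#' Gradient saliency map
#'
#' Backpropagates each segment's predicted-class probability to the input,
#' averages the gradient over the batch, takes the magnitude, and sums over
#' time to a per-channel score.  Channels deviating from the mean score by
#' more than 2 SD are dropped as outliers, and the map is normalized to
#' maximum 1.
#'
#' @param model a trained `eegnet_model`.
#' @param x C x T x N array of z-scored segments (N >= 1).
#' @param classes optional 1-based class index per segment; default the
#'   model's prediction.
#' @param pool batch composition before the `|mean(G)|` reduction:
#'   `"per_segment"` (default) treats every segment as its own batch and
#'   averages the per-segment magnitude maps — the most stable choice for
#'   channel localization; `"per_class"` computes one map per predicted
#'   class, max-normalizes and averages (group-level topography style);
#'   `"all"` uses the whole batch as one group.
#' @return tibble (class `saliency_map`): `channel`; `saliency`, the
#'   outlier-filtered map normalized to maximum 1 (`NA` for removed
#'   channels); `kept`, the outlier flag; `raw`, the unfiltered map
#'   normalized to maximum 1 (use this for channel-localization analyses —
#'   the 2-SD rule exists for group-level topography display and can remove
#'   genuinely dominant channels).
#' @export
saliency_map <- function(model, x, classes = NULL,
                         pool = c("per_segment", "per_class", "all")) {
  stopifnot(inherits(model, "eegnet_model"))
  pool <- match.arg(pool)
  d <- dim(x)
  if (length(d) == 2) x <- array(x, c(d, 1))
  if (dim(x)[3] < 1) stop("empty batch", call. = FALSE)
  cspec <- .cpp_spec(model$spec)
  if (is.null(classes)) {
    p <- eegnet_forward_cpp(model$par, cspec, x)
    classes <- max.col(t(p))
  }
  classes <- as.integer(classes)
  G <- eegnet_input_grad(model$par, cspec, x, classes - 1L)
  one_map <- function(idx) {
    S_t <- abs(apply(G[, , idx, drop = FALSE], c(1, 2), mean))  # C x T
    rowSums(S_t)
  }
  S <- if (pool == "per_segment") {
    rowSums(apply(abs(G), c(1, 2), mean))
  } else if (pool == "per_class") {
    groups <- split(seq_along(classes), classes)
    maps <- lapply(groups, function(idx) {
      s <- one_map(idx)
      s / max(s)
    })
    Reduce(`+`, maps) / length(maps)
  } else one_map(seq_along(classes))
  dev <- abs(S - mean(S))
  kept <- dev <= 2 * stats::sd(S)
  s_norm <- S / max(S[kept])
  s_norm[!kept] <- NA_real_
  nm <- if (!is.null(model$channel_names)) model$channel_names
        else paste0("ch", seq_along(S))
  structure(tibble::tibble(channel = nm, saliency = s_norm, kept = kept,
                           raw = S / max(S)),
            class = c("saliency_map", class(tibble::tibble())))
}
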