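# Filter-bank common spatial patterns with LDA.
#
# Per frequency band: zero-phase band-pass, CSP spatial filters from the
# class-average segment covariances, log-variance features; features across
# the bank are ranked by mutual information with the labels and the top k
# feed an LDA.  Multi-class problems are handled one-vs-rest with a
# max-posterior decision.

#' Common spatial pattern filters for a class pair
#'
#' Solves the generalized eigenproblem `cov_a w = lambda (cov_a + cov_b) w`
#' via whitening of the composite covariance and returns the `n_pairs`
#' largest- and `n_pairs` smallest-lambda filters, normalized so that
#' `t(W) %*% (cov_a + cov_b) %*% W = I` on the selected columns.
#'
#' @param cov_a,cov_b symmetric positive definite channel covariances.
#' @param n_pairs filter pairs to keep.
#' @return matrix channels x (2 * n_pairs); eigenvalues in attribute
#'   `"lambda"` (descending).
#' @export
csp_fit <- function(cov_a, cov_b, n_pairs = 2) {
  Rc <- (cov_a + cov_b)
  Rc <- (Rc + t(Rc)) / 2
  ec <- eigen(Rc, symmetric = TRUE)
  tol <- 1e-10 * max(ec$values)
  if (min(ec$values) < tol) {
    warning("near-singular composite covariance; shrinkage applied",
            call. = FALSE)
    lam <- 1e-6 * sum(diag(Rc)) / nrow(Rc)
    Rc <- Rc + lam * diag(nrow(Rc))
    ec <- eigen(Rc, symmetric = TRUE)
  }
  Wh <- ec$vectors %*% diag(1 / sqrt(ec$values), nrow(Rc))
  S <- t(Wh) %*% cov_a %*% Wh
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)     # descending lambda
  W <- Wh %*% es$vectors
  sel <- c(seq_len(n_pairs), nrow(Rc) - seq_len(n_pairs) + 1)
  structure(W[, sel, drop = FALSE], lambda = es$values[sel])
}

#' Default filter bank: nine 4-Hz bands, 4-40 Hz
#' @return list of `c(low, high)` pairs.
#' @export
fbcsp_bands <- function() lapply(0:8, function(i) c(4 + 4 * i, 8 + 4 * i))

# histogram mutual information between a continuous feature and labels
.mi_feature <- function(f, y, n_bins = 8) {
  br <- unique(stats::quantile(f, seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) return(0)
  b <- cut(f, br, include.lowest = TRUE)
  tab <- table(b, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

# band-pass every trial of a set (zero-phase), returning the filtered array
.filter_trials <- function(ts, band, order = 4) {
  hi <- min(band[2], ts$fs / 2 * 0.99)
  coef <- butter_design(ts$fs, band[1], hi, order)
  out <- ts$data
  for (i in seq_len(n_trials(ts)))
    out[i, , ] <- filtfilt_mat(coef, ts$data[i, , ])
  out
}

# segment-level log-variance features after projecting with W
.csp_features <- function(xfilt, W, seg_idx) {
  t(vapply(seq_len(dim(xfilt)[3]), function(i) {
    pr <- t(W) %*% xfilt[, , i]
    log(pmax(rowMeans(pr^2), 1e-300))
  }, numeric(ncol(W))))
}

#' Fit the filter-bank CSP + LDA decoder
#'
#' @param ts a [trial_set()] at the decoding rate.
#' @param bands list of band edges, default [fbcsp_bands()].
#' @param n_pairs CSP filter pairs per band (2).
#' @param k_features features kept by mutual-information ranking, per binary
#'   problem (4); capped with a warning when fewer are available.
#' @param window_s,step_s segmentation of trials (1 s / 125 ms).
#' @return An `fbcsp_model`.
#' @export
fbcsp_fit <- function(ts, bands = fbcsp_bands(), n_pairs = 2, k_features = 4,
                      window_s = 1, step_s = 0.125) {
  stopifnot(inherits(ts, "trial_set"))
  if (length(unique(ts$labels)) < 2)
    stop("need at least 2 classes", call. = FALSE)
  wlen <- round(window_s * ts$fs)
  step <- step_s * ts$fs

  # filter each trial per band, then cut into segments
  seg_of_band <- lapply(bands, function(bd) {
    xf <- .filter_trials(ts, bd)
    tlen <- dim(xf)[3]
    K <- floor((tlen - wlen) / step + 1e-9) + 1
    C <- dim(xf)[2]
    nt <- dim(xf)[1]
    segs <- array(0, c(C, wlen, nt * K))
    i <- 0
    for (tr in seq_len(nt))
      for (k in seq_len(K) - 1) {
        i <- i + 1
        s0 <- round(k * step)
        segs[, , i] <- xf[tr, , (s0 + 1):(s0 + wlen)]
      }
    segs
  })
  nt <- n_trials(ts)
  K <- dim(seg_of_band[[1]])[3] / nt
  seg_trial <- rep(seq_len(nt), each = K)
  seg_label <- ts$labels[seg_trial]

  n_feat_avail <- length(bands) * 2 * n_pairs
  if (k_features > n_feat_avail) {
    warning("k_features capped at ", n_feat_avail, call. = FALSE)
    k_features <- n_feat_avail
  }
  classes <- ts$class_set
  problems <- lapply(classes, function(cl) {
    ybin <- factor(ifelse(seg_label == cl, cl, "rest"), c(cl, "rest"))
    per_band <- lapply(seg_of_band, function(segs) {
      cov_sum <- function(idx) {
        S <- 0
        for (i in idx) {
          xc <- segs[, , i]
          cc <- tcrossprod(xc) / ncol(xc)
          S <- S + cc / sum(diag(cc))
        }
        S <- S / length(idx)
        # narrowband segments are rank-deficient; ledoit-style scalar
        # shrinkage keeps the composite covariance well conditioned
        S + (1e-6 * sum(diag(S)) / nrow(S)) * diag(nrow(S))
      }
      W <- csp_fit(cov_sum(which(ybin == cl)), cov_sum(which(ybin == "rest")),
                   n_pairs)
      feat <- .csp_features(segs, W, NULL)
      list(W = W, feat = feat)
    })
    feats <- do.call(cbind, lapply(per_band, `[[`, "feat"))
    mi <- apply(feats, 2, .mi_feature, y = ybin)
    sel <- order(mi, decreasing = TRUE)[seq_len(k_features)]
    lda <- MASS::lda(feats[, sel, drop = FALSE], grouping = ybin)
    list(class = cl, W = lapply(per_band, `[[`, "W"), sel = sel, lda = lda)
  })
  structure(list(problems = problems, bands = bands, classes = classes,
                 n_pairs = n_pairs, fs = ts$fs,
                 window_s = window_s, step_s = step_s),
            class = "fbcsp_model")
}

#' @export
print.fbcsp_model <- function(x, ...) {
  cat(sprintf("<fbcsp_model> %d bands x %d CSP pairs, classes: %s\n",
              length(x$bands), x$n_pairs, paste(x$classes, collapse = ", ")))
  invisible(x)
}

# per-segment class scores for an fbcsp model; x is a trial_set
#' Class probabilities from the FBCSP decoder
#'
#' @param object an `fbcsp_model`.
#' @param ts a [trial_set()] to score.
#' @param ... unused.
#' @return list with `proba` (segments x classes, rows sum to 1), `trial`
#'   (parent trial index per segment).
#' @export
predict.fbcsp_model <- function(object, ts, ...) {
  wlen <- round(object$window_s * ts$fs)
  step <- object$step_s * ts$fs
  nt <- n_trials(ts)
  seg_of_band <- lapply(object$bands, function(bd) {
    xf <- .filter_trials(ts, bd)
    tlen <- dim(xf)[3]
    K <- floor((tlen - wlen) / step + 1e-9) + 1
    segs <- array(0, c(dim(xf)[2], wlen, nt * K))
    i <- 0
    for (tr in seq_len(nt))
      for (k in seq_len(K) - 1) {
        i <- i + 1
        s0 <- round(k * step)
        segs[, , i] <- xf[tr, , (s0 + 1):(s0 + wlen)]
      }
    segs
  })
  scores <- NULL
  for (pi in seq_along(object$problems)) {
    pr <- object$problems[[pi]]
    feats <- do.call(cbind, lapply(seq_along(object$bands), function(bi)
      .csp_features(seg_of_band[[bi]], pr$W[[bi]], NULL)))
    post <- stats::predict(pr$lda, feats[, pr$sel, drop = FALSE])$posterior
    scores <- cbind(scores, post[, pr$class])
  }
  colnames(scores) <- object$classes
  K <- nrow(scores) / nt
  proba <- scores / rowSums(scores)
  list(proba = proba, trial = rep(seq_len(nt), each = K))
}
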