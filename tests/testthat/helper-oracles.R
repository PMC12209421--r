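# Independent oracles shared across test files.

# brute-force generalized eigendecomposition for CSP:
# cov_a w = lambda (cov_a + cov_b) w via a plain non-symmetric eigen of
# solve(Rc) %*% cov_a, columns normalized to w' Rc w = 1
csp_bruteforce <- function(cov_a, cov_b, n_pairs) {
  Rc <- cov_a + cov_b
  e <- eigen(solve(Rc) %*% cov_a)
  ord <- order(Re(e$values), decreasing = TRUE)
  V <- Re(e$vectors[, ord])
  lam <- Re(e$values[ord])
  for (j in seq_len(ncol(V)))
    V[, j] <- V[, j] / sqrt(drop(t(V[, j]) %*% Rc %*% V[, j]))
  sel <- c(seq_len(n_pairs), ncol(V) - seq_len(n_pairs) + 1)
  list(W = V[, sel, drop = FALSE], lambda = lam[sel])
}

# trial set of per-trial sinusoids with a controlled task-period amplitude
# scale (t0 seconds of pre-onset context at scale 1)
sine_trials <- function(n = 6, C = 3, fs = 100, t0 = 2, trial_s = 3,
                        freq = 10, amp = 5, task_scale = 1, noise = 0) {
  len <- round((t0 + trial_s) * fs)
  tt <- (seq_len(len) - 1) / fs - t0
  scale <- ifelse(tt >= 0, task_scale, 1)
  dat <- array(0, c(n, C, len))
  set.seed(99)
  for (i in seq_len(n)) {
    ph <- stats::runif(1, 0, 2 * pi)
    base <- amp * scale * sin(2 * pi * freq * tt + ph)
    for (c in seq_len(C))
      dat[i, c, ] <- base + if (noise > 0) stats::rnorm(len, sd = noise) else 0
  }
  trial_set(dat, rep("thumb", n), fs, t0 = t0,
            class_set = "thumb",
            channel_names = c("C3", "Cz", "C4"),
            positions = standard_montage(c("C3", "Cz", "C4")))
}

rand_spd <- function(C) {
  A <- matrix(rnorm(C * C), C)
  crossprod(A) / C + diag(C) * 0.1
}
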