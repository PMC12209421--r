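# Synthetic sensorimotor EEG sessions.
#
# The generative model, chosen so that every downstream quantity has a
# closed-form expectation:
#
#   x(c, t) = [K w]_c(t)                          spatially smoothed 1/f noise
#           + g_com[c] m_c(t) (A_a sin(2 pi 10 t + phi_a)
#                              + A_b sin(2 pi 20 t + phi_b))
#           + MRCP template + artifact bursts (optional)
#
# The background w is synthesized in the frequency domain (amplitude
# proportional to 1/sqrt(f)), mixed through a distance-based kernel K with
# unit-L2 rows, so the per-channel band power of the noise is an exact sum
# over FFT bins.  The sensorimotor rhythm rides on a common topography g_com
# (max 1 near C3); during a trial of class z its amplitude at channel c is
# multiplied by (1 - erd_depth * ramp(t) * gz[c]) where gz is the class
# topography scaled to max 1 — a class-specific multiplicative ERD with full
# depth at the class's peak channel.

#' Synthetic session configuration
#'
#' @param n_channels number of electrodes (montage channels), default 32.
#' @param fs sampling rate in Hz, default 256.
#' @param class_set subset of thumb/index/middle/pinky.
#' @param trials_per_class trials per finger class.
#' @param trial_s trial length in seconds (3 online-style, 5 offline-style).
#' @param iti_s inter-trial interval (s).
#' @param onset_jitter_s uniform jitter added to each trial onset (s), so
#'   the rhythm phase is not locked to the trial grid; default 0.25.
#' @param erd_depth fractional task-period amplitude reduction of the
#'   sensorimotor rhythm at the class's peak channel, in \[0, 1\].
#' @param overlap target cosine similarity between the topographies of the
#'   most adjacent finger pair (index-middle), in \[0, 1\].
#' @param snr rhythm-to-background amplitude ratio in the alpha band at the
#'   topography peak channel.
#' @param mrcp_amplitude movement-related cortical potential trough amplitude
#'   (microvolts, >= 0; 0 disables the component).
#' @param session_drift magnitude of the cross-session channel-space
#'   rotation/gain perturbation applied by [drift_session()].
#' @param artifact_rate fraction of trials receiving a high-amplitude
#'   low-frequency artifact burst.
#' @param artifact_sd artifact burst amplitude (microvolts SD).
#' @param noise_sd broadband background SD per channel (microvolts).
#' @param rhythm_variability relative amplitude of the slow (~0.05-0.8 Hz)
#'   waxing-and-waning envelope of the sensorimotor rhythm, in \[0, 1);
#'   0 gives a constant-amplitude rhythm.  The envelope is calibrated so
#'   the mean rhythm band power is unchanged.
#' @param spatial_mixing_mm length scale (mm) of the spatial correlation of
#'   the background noise; 0 gives channel-independent noise.
#' @param beta_ratio beta (20 Hz) amplitude as a fraction of alpha, default 0.5.
#' @param seed integer seed fixing all randomness.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_channels = 32, fs = 256,
                         class_set = c("thumb", "pinky"),
                         trials_per_class = 20, trial_s = 3, iti_s = 2,
                         onset_jitter_s = 0.25,
                         erd_depth = 0.6, overlap = 0.2, snr = 2,
                         mrcp_amplitude = 0, session_drift = 0,
                         artifact_rate = 0, artifact_sd = 60,
                         noise_sd = 10, spatial_mixing_mm = 35,
                         rhythm_variability = 0.5, beta_ratio = 0.5,
                         seed = 1) {
  stopifnot(erd_depth >= 0, erd_depth <= 1, overlap >= 0, overlap <= 1,
            trial_s > 1, fs > 0, n_channels >= 2,
            all(class_set %in% c("thumb", "index", "middle", "pinky")),
            length(class_set) >= 1)
  structure(list(n_channels = n_channels, fs = fs, class_set = class_set,
                 trials_per_class = trials_per_class, trial_s = trial_s,
                 iti_s = iti_s, onset_jitter_s = onset_jitter_s,
                 erd_depth = erd_depth, overlap = overlap,
                 snr = snr, mrcp_amplitude = mrcp_amplitude,
                 session_drift = session_drift,
                 artifact_rate = artifact_rate, artifact_sd = artifact_sd,
                 noise_sd = noise_sd, spatial_mixing_mm = spatial_mixing_mm,
                 rhythm_variability = rhythm_variability,
                 beta_ratio = beta_ratio,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# evaluate code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# somatotopic loci along the central-sulcus axis near C3, arc coordinates;
# spacing thumb-index : index-middle : middle-pinky = 1.5 : 1 : 1.5 so that
# sim(index, middle) > sim(thumb, index) > sim(thumb, pinky).  `step` is the
# arc (degrees) of one unit gap.
.finger_loci <- function(step = 5) {
  start <- c(ant = -3, lat = 58)           # lateral-inferior (thumb)
  dirn <- c(ant = 0.3, lat = -0.954)       # toward medial-superior
  s <- c(thumb = 0, index = 1.5, middle = 2.5, pinky = 4) * step
  t(vapply(s, function(si) .arc_to_xyz(start["ant"] + si * dirn["ant"],
                                       start["lat"] + si * dirn["lat"]),
           numeric(3)))
}

#' Per-class spatial topographies
#'
#' Gaussian gain bumps centered at per-finger scalp loci ordered along the
#' somatotopic axis near C3.  The bump width is solved (bisection on the
#' realized discrete cosine) so that the cosine similarity of the
#' index-middle pair meets `cfg$overlap`; the fixed 1.5 : 1 : 1.5 locus
#' spacing then guarantees sim(index,middle) > sim(thumb,index) >
#' sim(thumb,pinky).
#'
#' @param cfg a [synth_config()].
#' @param montage tibble of channel positions (columns `channel,x,y,z`);
#'   default the standard montage for `cfg$n_channels`.
#' @return named list of unit-L2 gain vectors (class `class_topographies`),
#'   with attributes `loci` and `sigma`.
#' @export
make_topographies <- function(cfg, montage = standard_montage(cfg$n_channels)) {
  if (!all(c("x", "y", "z") %in% names(montage)))
    stop("montage must carry 3-D positions", call. = FALSE)
  pos <- as.matrix(montage[, c("x", "y", "z")])
  bump <- function(locus, sigma) {
    d2 <- rowSums((pos - matrix(locus, nrow(pos), 3, byrow = TRUE))^2)
    g <- exp(-d2 / (2 * sigma^2))
    g / sqrt(sum(g^2))
  }
  cossim <- function(a, b) sum(a * b)
  target <- max(cfg$overlap, 0.02)
  nearest <- function(locus)
    which.min(rowSums((pos - matrix(locus, nrow(pos), 3, byrow = TRUE))^2))

  # widen the locus spacing until the montage resolves the fingers (each
  # locus has its own dominant electrode), then bisect the bump width so
  # the realized index-middle cosine meets the target
  step <- 5; loci <- NULL; sigma <- NA; sims <- NULL
  for (attempt in 1:14) {
    loci <- .finger_loci(step)
    if (length(unique(apply(loci, 1, nearest))) == 4) {
      sim_im <- function(s)
        cossim(bump(loci["index", ], s), bump(loci["middle", ], s))
      lo <- 1; hi <- 400
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (sim_im(mid) < target) lo <- mid else hi <- mid
      }
      sigma <- (lo + hi) / 2
      g <- lapply(rownames(loci), function(cl) bump(loci[cl, ], sigma))
      names(g) <- rownames(loci)
      sims <- c(im = cossim(g$index, g$middle),
                ti = cossim(g$thumb, g$index),
                tp = cossim(g$thumb, g$pinky))
      if (sims["im"] >= target - 0.03 && sims["im"] > sims["ti"] &&
          sims["ti"] > sims["tp"]) break
    }
    step <- step * 1.2
  }
  out <- lapply(cfg$class_set, function(cl) bump(loci[cl, ], sigma))
  names(out) <- cfg$class_set
  structure(out, loci = loci[cfg$class_set, , drop = FALSE], sigma = sigma,
            sims = sims, step = step,
            class = "class_topographies")
}

# 1/f spectral amplitude shape for an n-sample record at rate fs, scaled so
# the per-channel broadband SD is `sd_uV`; returns the amplitude per FFT bin
.noise_shape <- function(n, fs, sd_uV) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided
  a <- 1 / sqrt(pmax(f, 1))
  a[1] <- 0                                 # no DC
  a * sd_uV / sqrt(mean(a^2))
}

# exact per-channel noise band power implied by the synthesis
.noise_band_power <- function(n, fs, sd_uV, band) {
  a <- .noise_shape(n, fs, sd_uV)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sum(a[f >= band[1] & f <= band[2]]^2) / n
}

# spatial smoothing kernel with unit-L2 rows (preserves per-channel variance)
.mixing_kernel <- function(pos, scale_mm = 35) {
  d <- as.matrix(stats::dist(pos))
  K <- exp(-d^2 / (2 * scale_mm^2))
  K / sqrt(rowSums(K^2))
}

# ERD amplitude factor over a trial's samples: ramps 0 -> full depth over
# 0.3 s at onset, back over 0.3 s after the trial ends (handled by caller)
.erd_ramp <- function(n, fs, ramp_s = 0.3) {
  r <- round(ramp_s * fs)
  c(seq(0, 1, length.out = r), rep(1, max(0, n - r)))[seq_len(n)]
}

.mrcp_template <- function(t, amp) {
  # Gabor-like negative deflection: trough at ~0.4 s, back to baseline well
  # before 1.5 s, spectral content concentrated in ~0.5-2.5 Hz
  -amp * exp(-(t - 0.4)^2 / (2 * 0.18^2)) * cos(2 * pi * 1.4 * (t - 0.4))
}

#' Generate one synthetic session
#'
#' Produces a continuous multichannel recording with randomized balanced
#' trial order, 1/f spatially correlated background, 10/20 Hz sensorimotor
#' rhythms with class-specific ERD, and optional MRCP transients and
#' artifact trials.  Identical configuration and seed give a bit-identical
#' record.
#'
#' @param cfg a [synth_config()].
#' @param topographies optional list of per-class gain vectors overriding
#'   [make_topographies()] (e.g. topographies with known support for saliency
#'   experiments).
#' @return An [eeg_recording()]; the generative ground truth (topographies,
#'   amplitudes, trial table) is attached as attribute `"generator"`.
#' @export
generate_session <- function(cfg, topographies = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  montage <- standard_montage(cfg$n_channels)
  pos <- as.matrix(montage[, c("x", "y", "z")])
  if (is.null(topographies)) topographies <- make_topographies(cfg, montage)
  Z <- length(cfg$class_set)
  n_tr <- cfg$trials_per_class * Z
  lead_in <- 3; lead_out <- 2 + cfg$onset_jitter_s
  dur <- lead_in + n_tr * (cfg$trial_s + cfg$iti_s) + lead_out
  n <- round(dur * cfg$fs)
  C <- cfg$n_channels

  g_mrcp <- rep(0, C)
  with_seed(cfg$seed, {
    labels <- sample(rep(cfg$class_set, cfg$trials_per_class))
    onsets <- lead_in + (seq_len(n_tr) - 1) * (cfg$trial_s + cfg$iti_s) +
      stats::runif(n_tr, 0, cfg$onset_jitter_s)

    # background noise, exact 1/f spectrum, spatially mixed
    shape <- .noise_shape(n, cfg$fs, cfg$noise_sd)
    noise <- matrix(0, C, n)
    for (c in seq_len(C)) {
      w <- stats::rnorm(n)
      noise[c, ] <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
    }
    K <- if (cfg$spatial_mixing_mm > 0) .mixing_kernel(pos, cfg$spatial_mixing_mm)
         else diag(C)
    noise <- K %*% noise

    # sensorimotor rhythm through the common topography
    g_com <- {
      ctr <- colMeans(attr(topographies, "loci") %||% .finger_loci())
      d2 <- rowSums((pos - matrix(ctr, C, 3, byrow = TRUE))^2)
      g <- exp(-d2 / (2 * (45)^2))
      g / max(g)
    }
    p_alpha <- .noise_band_power(n, cfg$fs, cfg$noise_sd, c(8, 13))
    A_a <- cfg$snr * sqrt(2 * p_alpha)
    A_b <- cfg$beta_ratio * A_a
    tt <- (seq_len(n) - 1) / cfg$fs
    phi_a <- stats::runif(1, 0, 2 * pi); phi_b <- stats::runif(1, 0, 2 * pi)
    rhythm_t <- A_a * sin(2 * pi * 10 * tt + phi_a) +
      A_b * sin(2 * pi * 20 * tt + phi_b)
    env <- rep(1, n)
    if (cfg$rhythm_variability > 0) {
      # slow global envelope, unit mean square
      eshape <- rep(0, n)
      f <- (seq_len(n) - 1) * cfg$fs / n
      f <- pmin(f, cfg$fs - f)
      eshape[f >= 0.05 & f <= 0.8] <- 1
      b <- Re(stats::fft(stats::fft(stats::rnorm(n)) * eshape,
                         inverse = TRUE)) / n
      b <- (b - mean(b)) / stats::sd(b)
      env <- sqrt(pmax(0, 1 + cfg$rhythm_variability * b))
      env <- env / sqrt(mean(env^2))
      rhythm_t <- rhythm_t * env
    }

    # per-channel amplitude modulation: 1 during rest, 1 - d*gz during task
    mod <- matrix(1, C, n)
    trial_len <- round(cfg$trial_s * cfg$fs)
    ramp <- .erd_ramp(trial_len, cfg$fs)
    down <- round(0.3 * cfg$fs)
    for (i in seq_len(n_tr)) {
      s0 <- round(onsets[i] * cfg$fs)
      gz <- topographies[[labels[i]]]
      gz <- gz / max(gz)
      idx <- (s0 + 1):(s0 + trial_len)
      mod[, idx] <- mod[, idx] - cfg$erd_depth * outer(gz, ramp)
      # release ramp after trial end
      rel <- (s0 + trial_len + 1):min(s0 + trial_len + down, n)
      mod[, rel] <- mod[, rel] -
        cfg$erd_depth * outer(gz, seq(1, 0, length.out = length(rel)))
    }
    x <- noise + (g_com * mod) * matrix(rhythm_t, C, n, byrow = TRUE)

    # MRCP: fronto-central-to-parietal transient after each onset
    if (cfg$mrcp_amplitude > 0) {
      ctr <- .arc_to_xyz(8, 25)     # between FCz/C1 and C3
      d2 <- rowSums((pos - matrix(ctr, C, 3, byrow = TRUE))^2)
      g_mrcp <- exp(-d2 / (2 * 40^2))
      mr_len <- round(1.5 * cfg$fs)
      templ <- .mrcp_template((seq_len(mr_len) - 1) / cfg$fs,
                              cfg$mrcp_amplitude)
      for (i in seq_len(n_tr)) {
        s0 <- round(onsets[i] * cfg$fs)
        idx <- (s0 + 1):(s0 + mr_len)
        x[, idx] <- x[, idx] + outer(g_mrcp, templ)
      }
    }

    # artifact trials: large low-frequency bursts, frontal-weighted
    artifact_trials <- integer()
    if (cfg$artifact_rate > 0) {
      artifact_trials <- which(stats::runif(n_tr) < cfg$artifact_rate)
      g_art <- {
        front <- pos[, 2] - min(pos[, 2])
        g <- 0.3 + 0.7 * front / max(front)
        g <- g - mean(g)       # zero common mode: survives re-referencing
        g / sqrt(mean(g^2))    # unit RMS: burst SD == artifact_sd
      }
      for (i in artifact_trials) {
        s0 <- round(onsets[i] * cfg$fs)
        idx <- (s0 + 1):(s0 + trial_len)
        aw <- stats::rnorm(trial_len)
        f <- (seq_len(trial_len) - 1) * cfg$fs / trial_len
        f <- pmin(f, cfg$fs - f)
        af <- as.numeric(f >= 2 & f <= 15)   # survives the 2-30 Hz chain
        burst <- Re(stats::fft(stats::fft(aw) * af, inverse = TRUE)) / trial_len
        burst <- burst * cfg$artifact_sd / stats::sd(burst)
        x[, idx] <- x[, idx] + outer(g_art, burst)
      }
    }

    rec <- eeg_recording(x, cfg$fs, montage$channel,
                         positions = montage,
                         events = tibble::tibble(onset_s = onsets,
                                                 label = labels))
    attr(rec, "generator") <- list(cfg = cfg, topographies = topographies,
                                   g_com = g_com, A_alpha = A_a, A_beta = A_b,
                                   mixing = K, n = n, envelope = env,
                                   g_mrcp = g_mrcp,
                                   artifact_trials = artifact_trials)
    rec
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply deterministic cross-session drift
#'
#' Emulates day-to-day nonstationarity: a small orthogonal rotation in
#' channel space (Cayley transform of a random skew-symmetric matrix scaled
#' by `cfg$session_drift`), per-channel gain jitter and a global
#' baseline-power shift.  `day = 0` or `session_drift = 0` return the input
#' unchanged; the perturbation is a pure function of `(cfg$seed, day)`.
#'
#' @param rec an [eeg_recording()].
#' @param cfg the [synth_config()] that produced it.
#' @param day session index (0 = reference day).
#' @return The drifted recording.
#' @export
drift_session <- function(rec, cfg, day) {
  stopifnot(inherits(rec, "eeg_recording"), cfg$session_drift >= 0)
  if (day == 0 || cfg$session_drift == 0) return(rec)
  C <- nrow(rec$samples)
  with_seed(cfg$seed + 7919L * as.integer(day), {
    S <- matrix(stats::rnorm(C * C), C, C)
    S <- (S - t(S)) / sqrt(2 * C)            # skew-symmetric, O(1) scale
    aS <- cfg$session_drift * S
    R <- solve(diag(C) - aS, diag(C) + aS)   # Cayley: orthogonal
    gain <- 1 + cfg$session_drift * stats::rnorm(C, 0, 0.5)
    gain <- pmax(gain, 0.2)
    power <- 1 + cfg$session_drift * stats::rnorm(1, 0, 0.3)
    rec$samples <- (gain * (R %*% rec$samples)) * max(power, 0.2)
    rownames(rec$samples) <- rec$channel_names
  })
  rec
}

#' Closed-form expected ERD under the generative model
#'
#' Integrates the known generative spectrum (sinusoidal rhythm plus exact
#' 1/f band noise) against the Morlet filter bank used by [erd_map()],
#' including the effect of the common average reference, and returns the
#' expected ERD (percent) at each class's peak channel.  Serves as the
#' generator-side oracle for ERD recovery checks; it never runs the
#' measurement pipeline.
#'
#' @param rec a session from [generate_session()] (its `"generator"`
#'   attribute carries the ground truth).
#' @param band analysis band (Hz), default alpha `c(8, 13)`.
#' @param n_cycles Morlet cycles assumed by the measurement, default 7.
#' @return tibble with `class`, `channel` (peak channel name), `erd_expected`.
#' @export
expected_erd <- function(rec, band = c(8, 13), n_cycles = 7) {
  gen <- attr(rec, "generator")
  if (is.null(gen)) stop("recording lacks generator ground truth",
                         call. = FALSE)
  cfg <- gen$cfg
  C <- cfg$n_channels
  H <- diag(C) - matrix(1 / C, C, C)        # common average reference
  M <- H %*% gen$mixing                     # noise mixing after CAR
  freqs <- seq(band[1], band[2])
  wgain <- function(f0, f) exp(-(f - f0)^2 / (2 * (f0 / n_cycles)^2))

  # noise power through the wavelet bank, per channel (after CAR)
  n <- gen$n
  a <- .noise_shape(n, cfg$fs, cfg$noise_sd)
  f_bins <- (seq_len(n) - 1) * cfg$fs / n
  f_bins <- pmin(f_bins, cfg$fs - f_bins)
  keep <- f_bins > 0.5 & f_bins < 45        # wavelet support that matters
  wsum <- rowMeans(vapply(freqs, function(f0) wgain(f0, f_bins[keep])^2,
                          numeric(sum(keep))))
  p_noise_unit <- sum(a[keep]^2 * wsum) / n       # per unit row-norm
  p_noise <- rowSums(M^2) * p_noise_unit

  # rhythm power through the bank (10 and 20 Hz lines)
  g10 <- mean(wgain(freqs, 10)^2)
  g20 <- mean(wgain(freqs, 20)^2)
  purrr::map_dfr(cfg$class_set, function(cl) {
    gz <- gen$topographies[[cl]]
    gz <- gz / max(gz)
    peak <- which.max(gen$topographies[[cl]])
    base_gain <- as.vector(H %*% gen$g_com)
    task_gain <- as.vector(H %*% (gen$g_com * (1 - cfg$erd_depth * gz)))
    pb <- (gen$A_alpha * base_gain[peak])^2 / 2 * g10 +
      (gen$A_beta * base_gain[peak])^2 / 2 * g20
    pt <- (gen$A_alpha * task_gain[peak])^2 / 2 * g10 +
      (gen$A_beta * task_gain[peak])^2 / 2 * g20
    erd <- 100 * ((pt + p_noise[peak]) / (pb + p_noise[peak]) - 1)
    tibble::tibble(class = cl, channel = rec$channel_names[peak],
                   erd_expected = erd)
  })
}
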