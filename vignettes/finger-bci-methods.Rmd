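---
title: "Simulated closed-loop decoding of individual finger movements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated closed-loop decoding of individual finger movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fingerbci)
```

`fingerbci` studies a closed-loop noninvasive brain-computer interface in
which executed or imagined movements of single fingers of the right hand
drive a robotic hand, finger by finger. Because human EEG of this kind
requires subjects, hardware and many hours of recording, the package pairs
every analysis component with a seeded synthetic-session generator whose
statistical structure matches what the decoding chain assumes, so that the
whole loop — preprocessing, decoding, feedback, evaluation,
electrophysiology — is testable end to end on one desk.

## The signal model behind the generator

Executed and imagined finger movements suppress the sensorimotor alpha
(8–13 Hz) and beta (13–30 Hz) rhythms over the contralateral sensorimotor
cortex (event-related desynchronization, ERD), with spatial patterns that
overlap more for adjacent fingers (index–middle) than for distant ones
(thumb–pinky). The generator reproduces exactly this structure:

$$x_c(t) \;=\; [K\,w]_c(t)\;+\; g_c\, m_c(t)\, e(t)\,\big(A_\alpha \sin(2\pi 10 t + \phi_\alpha) + A_\beta \sin(2\pi 20 t + \phi_\beta)\big)\;+\;\text{MRCP}\;+\;\text{artifacts}$$

* **Background**: per-channel $1/f$ noise synthesized in the frequency
  domain (so its band power is an exact sum over FFT bins), mixed through a
  distance-based spatial kernel $K$ with unit-$L_2$ rows (per-channel
  variance preserved). `noise_sd` (default 10 µV) sets the broadband scale,
  `spatial_mixing_mm` (default 35 mm) the correlation length.
* **Rhythm**: 10 Hz and 20 Hz sinusoids projected through a common
  sensorimotor topography $g$ (Gaussian bump near C3, maximum 1).
  $A_\alpha$ is calibrated so that the alpha-band rhythm-to-background
  amplitude ratio at the peak channel equals `snr` (default 2); the beta
  amplitude is `beta_ratio` (0.5) of the alpha amplitude. A slow
  (0.05–0.8 Hz) global envelope $e(t)$ with unit mean square
  (`rhythm_variability`, default 0.5) gives the rhythm its realistic
  waxing-and-waning; without it every one-second window carries the same
  evidence and closed-loop traces are unrealistically stable.
* **ERD**: during a trial of class $z$, the rhythm amplitude at channel
  $c$ is multiplied by $1 - d\,\tilde g_{z,c}\,r(t)$, where $d$ is
  `erd_depth`, $\tilde g_z$ the class topography scaled to maximum 1, and
  $r(t)$ a 0.3-s onset ramp (and release ramp after trial end) that avoids
  an amplitude discontinuity. The full depth $d$ is therefore realized at
  the class's peak channel.
* **Class topographies** are Gaussian gain bumps at four loci ordered along
  the somatotopic axis near C3 with spacing ratio 1.5 : 1 : 1.5
  (thumb–index : index–middle : middle–pinky). The bump width is solved by
  bisection so the *realized, discretized* index–middle cosine similarity
  equals `overlap`; the spacing then enforces
  sim(index,middle) > sim(thumb,index) > sim(thumb,pinky). On sparse
  montages the loci spacing is automatically widened until each finger has
  a distinct dominant electrode — a 32-channel cap cannot resolve
  millimetre-scale somatotopy, and pretending otherwise would collapse all
  four topographies onto C3's indicator vector.
* **MRCP** (optional): a Gabor-like negative deflection (trough ≈ 0.4 s,
  spectral mass ≈ 0.5–2.5 Hz, back to baseline well before 1.5 s) at a
  fronto-central-to-parietal topography, amplitude `mrcp_amplitude`.
* **Artifacts** (optional): low-frequency high-amplitude bursts added to a
  fraction `artifact_rate` of trials, frontal-weighted, sized by
  `artifact_sd` so they trip the 20 µV rejection rule.
* **Cross-session drift**: `drift_session()` applies a Cayley-transform
  orthogonal rotation in channel space scaled by `session_drift`, plus
  per-channel gain jitter and a global power shift, all a pure function of
  (seed, day). Day 0 is the identity.
* **Trial structure**: balanced randomized classes, `trial_s` (3 s online
  style, 5 s offline style), `iti_s` = 2 s, and a small uniform onset
  jitter (`onset_jitter_s`, 0.25 s) so the global rhythm phase is not
  locked to the trial grid — phase locking would both leak oscillatory
  energy into trial-averaged slow potentials and hand decoders an
  unrealistic phase cue.

Everything is a pure function of `(config, seed, day)`; two calls with the
same arguments return bit-identical records.

### What the generator does not emulate

No biophysical head model (gains are geometric bumps, not lead fields); no
eye-blink or EMG waveform realism beyond amplitude inflation; no
non-stationarity within a session beyond the rhythm envelope; a single
global rhythm source rather than bilateral networks. Tests passing on this
generator therefore demonstrate that the pipeline recovers the structure it
assumes — not that it would reach any particular accuracy on human EEG.

## Preprocessing

The online chain is fixed, in order: common average reference → polyphase
resampling to 100 Hz → causal 4th-order Butterworth band-pass (4–40 Hz) →
sliding 1-s windows every 125 ms → per-window channel z-scoring
(population SD). Causality matters for the real-time contract: the IIR
filter carries explicit state, and chunk-by-chunk filtering equals
whole-record filtering to below 1e-9. The resampler is a Kaiser-windowed
polyphase FIR (60 dB design attenuation, passband to 0.7× and stopband from
0.9× the new Nyquist) with its group delay compensated; a 45 Hz tone
survives 1024→100 Hz resampling at below 1 % RMS.

The offline ERD chain is: common average reference → 100 Hz → 2–30 Hz
zero-phase band-pass → epochs from 2 s before onset to trial end →
rejection of trials whose flattened-trial population SD exceeds 20 µV.
Independent-component artifact removal is out of scope; the rejection rule
alone stands in for it, which is a stated limitation.

A z-scored window with a dead (flat) channel maps that channel to zeros
with a warning rather than failing — an online loop must survive a dead
electrode.

## Decoders

**Compact convolutional network (EEGNet-8,2 family).** Temporal
convolution (F1 = 8 kernels of half the sampling rate, 50 samples at
100 Hz) → batch-norm → depthwise spatial convolution across all channels
(depth multiplier D = 2, max-norm 1) → batch-norm → ELU → average-pool 4 →
dropout 0.5 → separable convolution (depthwise 16-sample kernels +
pointwise, F2 = 16) → batch-norm → ELU → average-pool 8 → dropout →
flatten → dense (max-norm 0.25) → softmax. The `deep` variant doubles the
filter counts and appends two further separable blocks before the flatten.
Forward, backward and input-gradient passes are implemented in compiled
code and verified against central finite differences to 1e-4 relative
error in the test suite.

Training uses cross-entropy, Adam (lr 1e-3 by default; the short synthetic
studies below use 3e-3), batch 64, a stratified trial-level validation
split (10 %), early stopping (patience 20) restoring the best-validation
weights, reduce-on-plateau (×0.5, patience 10), and decoupled weight decay
1e-3 on convolution and dense weights. The decay matters for
interpretability: with batch-norm after each convolution, weights that
carry no class information otherwise keep their random initialization
forever and contaminate gradient saliency. All randomness — initialization,
shuffling, dropout — is drawn from the R RNG, so a seed fixes training
bit-exactly (single-threaded deterministic mode is the test default).

**Fine-tuning** freezes the first four layers — the temporal convolution,
its batch-norm, the depthwise spatial convolution, and its batch-norm
(the normalizations travel with their convolutions), including their
running statistics — bit-exactly, and adapts the remaining layers to
same-day data.

**FBCSP + LDA.** Nine 4-Hz bands (4–8 … 36–40 Hz), zero-phase filtering,
common spatial patterns from class-average segment covariances (2 filter
pairs per band; Ledoit-style scalar shrinkage 1e-6·trace/C keeps the
narrowband composite covariances well conditioned), log-variance features,
the top 4 features per one-vs-rest problem by histogram mutual information
(8 quantile bins), and LDA with a max-posterior multi-class decision. The
CSP solver whitens the composite covariance and is checked against a
brute-force generalized eigendecomposition to 1e-8 up to sign.

**Cross-validation** is stratified at the trial level *before* windowing —
no segment of a held-out trial ever reaches training — and per-trial
predictions are the majority vote over that trial's window predictions.

## The closed loop

From 1 s after trial onset, every 125 ms for 2 s (a half-open feedback
interval: updates at 1.000, 1.125, …, 2.875 s — exactly 16), the most
recent 1-s preprocessed window is z-scored and decoded; the winning finger
flexes 0.1 rad; at trial end the finger that flexed most is the trial
prediction, with exact ties broken by the larger summed controlling
probability (ties in a single update fall to the lowest class index). With
the uniform 0.1-rad step this decision provably equals the majority vote of
per-update winners whenever there is no tie, which the tests confirm
exhaustively on random traces.

The probability smoother keeps an accumulator $h_0 = 0$,
$P'_t = \alpha h_{t-1} + P_t$, $h_t = P'_t$, and emits $P'_t$ normalized to
sum 1 ($L_1$). The accumulator is stored *pre*-normalization, following the
recursion as written; a post-normalization variant sits behind
`normalize_history`. Both are bounded, $\lVert h\rVert_1 \le 1/(1-\alpha)$.
The history weight α is not prescribed anywhere, so the default is
α = 0.75, exposed in the protocol and the CLI; the smoother resets to
$h = 0$ at each trial onset. At α = 0 the loop reduces bit-exactly to the
unsmoothed pipeline.

A full session decodes its first half with the base model, fine-tunes on
those trials, and decodes the second half with the fine-tuned model;
`replay_offline()` re-feeds identical windows to any set of models, and
replaying the online model reproduces the online log exactly.

## Electrophysiology

ERD is measured with 7-cycle complex Morlet wavelets on a 1-Hz grid across
the band, power calibrated so a sinusoid of amplitude $A$ reads $A^2/2$ at
its own frequency: per channel,
$\mathrm{ERD}_c = (P_c - \bar R_c)/\bar R_c \times 100\,\%$, with the task
window from 0.5 s after onset to trial end, the baseline the second before
onset, and $\bar R_c$ the session-average baseline power. The generator
also provides `expected_erd()`, the closed-form expectation of this
quantity under the generative model — integrating the known rhythm lines
and exact noise spectrum through the wavelet bank and the common-average
reference — which the measurement recovers within a few points at 50
trials. The wavelet cycle count and the 1-Hz grid are exposed because the
reference analyses do not state them; edge samples are not trimmed, which
biases the task-window estimate slightly toward baseline at both ends.

MRCP analysis re-references, resamples to 100 Hz, band-passes 0.3–3 Hz
(zero-phase, order 2 — low order keeps the low cut numerically tame),
epochs with 1 s of pre-onset context, subtracts the pre-onset mean, and
averages per class. `topography_distance()` reports the Euclidean distance
between the channels of maximum desynchronization of two maps.

## Design choices where the design was genuinely open

* **Montage**: idealized spherical 10-10 coordinates (85 mm radius)
  computed from arc angles; BioSemi bank names map to a deterministic
  synthetic spherical-cap lattice because the vendor cap's true
  bank-to-10-20 correspondence is not public. Unknown labels inherit the
  nearest mapped position with a warning.
* **Container**: the epoched/session container is a versioned single-file
  native serialization with the logical layout data / labels / fs / t0 /
  channels / positions (float64); round-trips are bit-exact.
* **Population SD** everywhere (z-scoring, rejection): deterministic and
  exactly testable.
* **Saliency**: gradient attribution — per-instance gradients of the
  predicted-class probability, reduced by batch-mean, magnitude, and a sum
  over time. How instances are grouped into batches before the mean is an
  open choice; the default treats each segment as its own batch and
  averages the per-segment magnitude maps, which is by far the most stable
  grouping for channel localization (larger batches cancel the
  oscillatory-phase-dependent gradient components that carry the channel
  information). Per-class and whole-batch groupings are provided as
  options. Channels deviating from the map mean by more than 2 SD are flagged
  and removed from the *display* map; localization analyses should rank the
  raw normalized map, because with a well-trained model on focal signal the
  2-SD rule removes precisely the dominant true channels.
* **Saliency localization experiment**: run without the common average
  reference and with spatially uncorrelated background. CAR copies
  −1/C of any focal source into every channel; with C = 32 that leak is
  large enough that a decoder can legitimately read the class from
  non-support channels, voiding the "signal confined to six channels"
  premise rather than testing attribution. With a constant-amplitude
  rhythm (no envelope) attribution is cleanest.
* **Smoothing study conditions**: moderate difficulty (ERD depth 0.45,
  SNR 1, envelope 0.7) chosen once so the raw decoder is good but not
  saturated — at the high-SNR defaults every update is correct, label
  shifts are zero with or without smoothing, and the comparison is vacuous.
* **Band-ablation design**: the band under test replaces the 4–40 Hz
  online band-pass (filter-then-decode), rather than re-filtering
  already-band-limited data.

## Problem sizes

The test suite and the acceptance script run the studies at desk scale,
chosen once: 32 channels at 256 Hz; 40 trials/class for the headline
cross-validation (20 training epochs at lr 3e-3, which the validation
curves show is past convergence on this generator); for the
drift/fine-tuning study, 10 seeds with 12 trials/class on the reference
day and 52 trials on the drifted day (drift 0.35; the first 22 trials
fine-tune at lr 1e-3, the remaining 30 evaluate); 25 training + 20×20
replay trials for the smoothing study; 15 trials/class over 5 seeds for
saliency localization; 50 trials/class for ERD recovery. A full run of
the suite takes roughly twelve minutes on one CPU core.

## Known limitations

Accuracies on this generator say nothing quantitative about human EEG: the
synthetic classes are far cleaner than real finger somatotopy seen through
volume conduction (real decoding of adjacent fingers from scalp EEG hovers
near chance). The generator's somatotopic spacing is widened to what the
montage can resolve, so "adjacent-finger" similarity is a controlled
parameter, not an anatomical prediction. ICA is replaced by amplitude
rejection. The deep-variant hyperparameters are plausible defaults, not a
published table. Group-level statistics (ANOVA, mixed models, cluster
permutation) are intentionally out of scope; per-session metrics are
emitted as tidy tables for external tools.
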