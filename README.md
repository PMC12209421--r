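# fingerbci

Simulated closed-loop EEG decoding of individual finger movements.

Noninvasive brain-computer interfaces can drive a robotic hand at the level
of single fingers: executed or imagined flexion of the thumb, index, middle
or pinky modulates sensorimotor rhythms over the contralateral motor
cortex, a decoder turns 1-second EEG windows into class probabilities every
125 ms, and the winning robotic finger flexes in real time. Studying such a
loop normally requires subjects, an EEG amplifier and a robotic hand.
`fingerbci` reproduces the whole computational loop at desk scale for
methods work: a seeded generator of sensorimotor EEG with class-specific
event-related desynchronization (ERD), the exact online preprocessing
chain, two decoder families, closed-loop simulation with probability
smoothing, the field's evaluation metrics, and wavelet electrophysiology.

The core pieces, in the field's standard notation:

* **ERD**, per channel c: `ERD_c = (P_c − R̄_c)/R̄_c × 100%`, with P_c the
  Morlet-wavelet band power (alpha 8–13 Hz or beta 13–30 Hz) in the task
  window and R̄_c the session-average baseline power in the second before
  trial onset.
* **Decoders**: a compact convolutional network of the EEGNet-8,2 family
  (temporal convolution → depthwise spatial convolution → separable
  convolution → softmax; training, cross-session fine-tuning with the first
  four layers frozen, and gradient saliency maps `S = Σ_t |mean(dP/dX)|`
  are all implemented from scratch, with compiled forward/backward passes
  verified against finite differences), and filter-bank common spatial
  patterns (nine 4-Hz bands, CSP by generalized eigendecomposition,
  mutual-information feature selection, LDA).
* **Closed-loop rule**: per update the winning finger flexes 0.1 rad; the
  trial prediction is the finger that flexed most (equivalently, the
  majority vote). An optional smoother `h_0 = 0; P'_t = α·h_{t−1} + P_t;
  h_t = P'_t`, with `P'_t` renormalized to sum 1, stabilizes the control;
  its effect is quantified by **Label Shifts** (winner changes within a
  trial) and the **All-Hit Ratio** (trials with every update correct).

## Worked example

Generate a two-finger session, train the convolutional decoder, and play a
fresh session through the closed loop with fine-tuning at half time:

```r
library(fingerbci)

cfg <- synth_config(trials_per_class = 20, erd_depth = 0.6, snr = 2, seed = 3)
rec <- generate_session(cfg)
rec
#> <eeg_recording> 32 channels x 52544 samples @ 256 Hz (205.2 s), 40 events

ts <- epoch_trials(preprocess_online(rec), 0, 3)
set.seed(11)
model <- build_eegnet(eegnet_spec(32, 100, 2))
model
#> <eegnet_model> standard variant: C=32 T=100 Z=2 (1602 trainable parameters) [untrained]
model <- train_eegnet(model, ts,
                      train_config(max_epochs = 15, patience = 6,
                                   lr = 3e-3, seed = 5))
glance(model)
#> # A tibble: 1 × 8
#>   variant  n_params n_channels n_samples n_classes epochs_trained best_val_loss best_val_acc
#>   <chr>       <dbl>      <int>     <int>     <int>          <int>         <dbl>        <dbl>
#> 1 standard     1602         32       100         2             15        0.0805            1

sess <- generate_session(synth_config(trials_per_class = 8, seed = 77))
out <- run_session(model, sess, online_protocol(), n_runs = 4,
                   finetune_after = 2,
                   train_cfg = train_config(max_epochs = 10, patience = 4,
                                            lr = 3e-3, seed = 9))
metric_report(out$results)
#> # A tibble: 1 × 5
#>   accuracy mean_label_shifts all_hit_ratio n_trials per_class
#>      <dbl>             <dbl>         <dbl>    <int> <list>
#> 1      100                 0           100       16 <tibble [2 × 4]>
```

The report reads: every trial's majority vote matched the cued finger
(accuracy 100%), the per-update winner never changed within a trial, and
every trial was decoded correctly at all of its 16 updates — at these
generator settings the task is easy; `scripts/acceptance.R` also exercises
harder regimes where smoothing visibly stabilizes flickering traces.

ERD topographies and the generator's closed-form expectation:

```r
erd_ts <- rec |> preprocess_erd() |> epoch_trials(-2, 3)
em <- erd_map(reject_trials(erd_ts)$trials)          # alpha band
expected_erd(rec)
#> # A tibble: 2 × 3
#>   class channel erd_expected
#>   <chr> <chr>          <dbl>
#> 1 thumb CP5            -25.4
#> 2 pinky FCz            -36.8
autoplot(em)      # per-class scalp topography of the measured ERD
```

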