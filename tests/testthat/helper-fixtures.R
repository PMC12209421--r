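# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, force(expr), .fixture_env)
  get(name, .fixture_env)
}

# default-condition session (20 trials/class) and its decoding trial set
fix_session <- function() memo("session", {
  generate_session(synth_config(trials_per_class = 20, seed = 3))
})

fix_trialset <- function() memo("trialset", {
  epoch_trials(preprocess_online(fix_session()), 0, 3)
})

# a compact trained decoder on the default session (used by online/metrics
# tests); short schedule, fixed seed
fix_model <- function() memo("model", {
  ts <- fix_trialset()
  set.seed(11)
  model <- build_eegnet(eegnet_spec(32, 100, 2))
  train_eegnet(model, ts,
               train_config(max_epochs = 15, patience = 6, lr = 3e-3,
                            seed = 5))
})

# small evaluation session from a different seed, same conditions
fix_eval_session <- function() memo("eval_session", {
  generate_session(synth_config(trials_per_class = 8, seed = 77))
})

random_simplex <- function(k) {
  p <- stats::runif(k)
  p / sum(p)
}

with_seed_labels <- function(labels, seed) {
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(labels)
}
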