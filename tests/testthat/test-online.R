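test_that("smoother recursion follows the weighted-sum definition", {
  # alpha = 0: identity
  st <- smoother_state(0, 2)
  out <- smooth_step(st, c(0.3, 0.7))
  expect_equal(out$P_smoothed, c(0.3, 0.7))

  # hand-worked two-step recursion at alpha = 0.5:
  # P1 = (0.6, 0.4) -> P'1 = (0.6, 0.4), h = (0.6, 0.4)
  # P2 = (0.5, 0.5) -> P'2 = (0.8, 0.7) -> normalized (8/15, 7/15)
  st <- smoother_state(0.5, 2)
  s1 <- smooth_step(st, c(0.6, 0.4))
  expect_equal(s1$P_smoothed, c(0.6, 0.4))
  s2 <- smooth_step(s1$state, c(0.5, 0.5))
  expect_equal(s2$P_smoothed, c(8 / 15, 7 / 15), tolerance = 1e-12)

  # constant input: geometric-series fixed point h* = P/(1-alpha), so the
  # normalized output converges back to P
  st <- smoother_state(0.5, 3)
  P <- c(0.2, 0.5, 0.3)
  for (i in 1:60) {
    out <- smooth_step(st, P)
    st <- out$state
  }
  expect_equal(out$P_smoothed, P, tolerance = 1e-10)

  expect_error(smoother_state(1, 2), "alpha")
  expect_error(smoother_state(-0.1, 2), "alpha")
  expect_error(smooth_step(smoother_state(0.5, 2), c(2, 3)), "probability")
})

test_that("smoother accumulator stays bounded by 1/(1 - alpha)", {
  for (alpha in c(0.25, 0.5, 0.75, 0.9)) {
    st <- smoother_state(alpha, 3)
    set.seed(17)
    worst <- 0
    for (i in 1:2000) {
      out <- smooth_step(st, random_simplex(3))
      st <- out$state
      worst <- max(worst, sum(abs(st$h)))
      expect_true(all(out$P_smoothed >= 0))
      expect_equal(sum(out$P_smoothed), 1, tolerance = 1e-12)
    }
    expect_lte(worst, 1 / (1 - alpha) + 1e-9)
  }
})

test_that("hand accumulation adds one step to the winning finger only", {
  hand <- stats::setNames(rep(0, 2), c("thumb", "pinky"))
  for (i in 1:3) hand <- hand_update(hand, "thumb")
  expect_equal(unname(hand), c(0.3, 0))
  hand2 <- stats::setNames(rep(0, 2), c("A", "B"))
  for (w in c("A", "B", "A")) hand2 <- hand_update(hand2, w)
  expect_equal(unname(hand2), c(0.2, 0.1))
  expect_error(hand_update(hand, "ring"), "unknown finger")
})

test_that("flexion argmax equals the majority vote on tie-free traces", {
  set.seed(23)
  n_checked <- 0
  for (i in 1:10000) {
    k <- sample(2:4, 1)
    U <- sample(c(8, 16), 1)
    cls <- paste0("f", seq_len(k))
    winners <- sample(cls, U, replace = TRUE)
    counts <- table(factor(winners, cls))
    if (sum(counts == max(counts)) > 1) next       # tie-free only
    n_checked <- n_checked + 1
    hand <- stats::setNames(rep(0, k), cls)
    for (w in winners) hand <- hand_update(hand, w)
    trace <- fingerbci:::probability_trace(
      seq_len(U), matrix(1 / k, U, k), matrix(1 / k, U, k),
      winners, cls, FALSE)
    expect_identical(trial_prediction(hand, trace),
                     majority_vote(winners, class_order = cls))
  }
  expect_gt(n_checked, 5000)
})

test_that("trial prediction breaks exact ties by summed probability", {
  hand <- c(A = 0.8, B = 0.8)
  raw <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  trace <- fingerbci:::probability_trace(1:2, raw, raw,
                                         c("A", "B"), c("A", "B"), FALSE)
  expect_identical(trial_prediction(hand, trace), "A")  # 1.1 vs 0.9
  expect_error(trial_prediction(hand, NULL), "empty")
})

test_that("the closed loop produces 16 updates and respects alpha = 0", {
  m <- fix_model()
  prep <- preprocess_online(fix_eval_session())
  ts <- epoch_trials(prep, 0, 3)
  tr <- ts$data[1, , ]
  out <- simulate_trial(m, tr, prep$fs, online_protocol())
  expect_length(out$trace$time_s, 16)
  expect_equal(out$trace$time_s[1], 1)
  expect_equal(out$trace$time_s[16], 2.875)
  expect_equal(rowSums(out$trace$raw), rep(1, 16), tolerance = 1e-6)
  expect_equal(sum(out$hand), 16 * 0.1, tolerance = 1e-12)
  expect_true(out$prediction %in% m$classes)

  # smoothing off vs alpha = 0: identical traces
  off <- simulate_trial(m, tr, prep$fs, online_protocol(smoothing = FALSE))
  a0 <- simulate_trial(m, tr, prep$fs,
                       online_protocol(smoothing = TRUE, alpha = 0))
  expect_identical(off$trace$winner, a0$trace$winner)
  expect_equal(off$trace$raw, a0$trace$smoothed, tolerance = 1e-12)

  short <- tr[, 1:150]
  expect_error(simulate_trial(m, short, prep$fs), "underrun")
})

test_that("a full session decodes both halves and fine-tunes in between", {
  m <- fix_model()
  sess <- fix_eval_session()
  out <- run_session(m, sess, online_protocol(), n_runs = 4,
                     finetune_after = 2,
                     train_cfg = train_config(max_epochs = 3, patience = 3,
                                              lr = 3e-3, seed = 9))
  expect_equal(nrow(out$results), 16)
  expect_setequal(unique(out$results$half), c("base", "finetuned"))
  expect_true(all(out$results$label_shifts >= 0 &
                    out$results$label_shifts <= 15))
  # frozen front end survived the in-session fine-tune
  expect_identical(out$model_finetuned$par$Wt, m$par$Wt)
  # determinism of the whole loop
  out2 <- run_session(m, sess, online_protocol(), n_runs = 4,
                      finetune_after = 2,
                      train_cfg = train_config(max_epochs = 3, patience = 3,
                                               lr = 3e-3, seed = 9))
  expect_identical(out$results$prediction, out2$results$prediction)
  expect_error(run_session(m, sess, n_runs = 5), "divide")
})
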