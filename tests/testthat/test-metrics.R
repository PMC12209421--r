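test_that("majority vote returns the mode with documented tie-breaks", {
  expect_identical(majority_vote(c("A", "A", "B")), "A")
  expect_identical(majority_vote(c("A", "B", "A", "B")), "A")  # index tie-break
  raw <- rbind(c(0.2, 0.8), c(0.9, 0.1), c(0.4, 0.6), c(0.45, 0.55))
  tr <- fingerbci:::probability_trace(1:4, raw, raw,
                                      c("B", "A", "B", "B"),
                                      c("A", "B"), FALSE)
  # tie A/B? winners are B,A,B,B -> no tie; craft one
  tr2 <- fingerbci:::probability_trace(1:4, raw, raw,
                                       c("A", "B", "A", "B"),
                                       c("A", "B"), FALSE)
  expect_identical(majority_vote(c("A", "B", "A", "B"), trace = tr2), "B")
  expect_error(majority_vote(character()), "empty")

  # brute-force count-and-argmax oracle over random draws
  set.seed(31)
  for (i in 1:10000) {
    cls <- paste0("c", 1:sample(2:4, 1))
    w <- sample(cls, 16, replace = TRUE)
    counts <- vapply(cls, function(cl) sum(w == cl), 0L)
    top <- cls[counts == max(counts)]
    expect_identical(majority_vote(w, class_order = cls), top[1])
  }
})

test_that("accuracy is the percentage of majority-correct trials", {
  res <- tibble::tibble(label = rep("A", 10),
                        prediction = c(rep("A", 8), "B", "B"))
  expect_equal(accuracy_pct(res), 80)
  expect_equal(accuracy_pct(tibble::tibble(label = "A", prediction = "A")),
               100)
  expect_error(accuracy_pct(res[0, ]), "no trials")

  # uniform-random predictions on 2 classes, 400 trials: inside [42, 58]
  set.seed(7)
  r <- tibble::tibble(label = rep(c("A", "B"), 200),
                      prediction = sample(c("A", "B"), 400, TRUE))
  expect_gt(accuracy_pct(r), 42)
  expect_lt(accuracy_pct(r), 58)
})

test_that("precision and recall match hand arithmetic on a known confusion", {
  # confusion [[8,2],[3,7]]: rows true A,B; cols predicted A,B
  res <- tibble::tibble(
    label = c(rep("A", 10), rep("B", 10)),
    prediction = c(rep("A", 8), rep("B", 2), rep("A", 3), rep("B", 7)))
  pr <- precision_recall(res)
  expect_equal(pr$precision[pr$class == "A"], 100 * 8 / 11, tolerance = 1e-9)
  expect_equal(pr$precision[pr$class == "B"], 100 * 7 / 9, tolerance = 1e-9)
  expect_equal(pr$recall[pr$class == "A"], 80)
  expect_equal(pr$recall[pr$class == "B"], 70)

  perfect <- tibble::tibble(label = c("A", "B"), prediction = c("A", "B"))
  prp <- precision_recall(perfect)
  expect_true(all(prp$precision == 100) && all(prp$recall == 100))

  # class never predicted: precision missing (NA), recall 0
  res2 <- tibble::tibble(label = c("A", "B"), prediction = c("A", "A"))
  pr2 <- precision_recall(res2, classes = c("A", "B"))
  expect_true(is.na(pr2$precision[pr2$class == "B"]))
  expect_equal(pr2$recall[pr2$class == "B"], 0)
})

test_that("label shifts count winner changes within a trial", {
  expect_equal(label_shifts(c("1", "1", "2", "2", "1")), 2)
  expect_equal(label_shifts(rep("x", 16)), 0)
  expect_equal(label_shifts(rep(c("a", "b"), 8)), 15)
  expect_error(label_shifts(character()), "empty")
})

test_that("all-hit ratio requires every update to be correct", {
  mk_trace <- function(w) fingerbci:::probability_trace(
    seq_along(w), matrix(0.5, length(w), 2), matrix(0.5, length(w), 2),
    w, c("A", "B"), FALSE)
  res <- tibble::tibble(
    label = c("A", "A", "B"),
    prediction = c("A", "A", "B"),
    trace = list(mk_trace(rep("A", 4)), mk_trace(rep("A", 4)),
                 mk_trace(c("B", "A", "B", "B"))))
  expect_equal(all_hit_ratio(res), 100 * 2 / 3, tolerance = 1e-9)
  # one wrong update spoils the trial even though the majority is correct
  one_bad <- res[3, ]
  expect_equal(all_hit_ratio(one_bad), 0)
})

test_that("all-hit implies zero shifts implies majority-correct on real runs", {
  m <- fix_model()
  out <- run_session(m, fix_eval_session(), online_protocol(), n_runs = 4,
                     finetune_after = 4, finetune = FALSE)
  r <- out$results
  for (i in seq_len(nrow(r))) {
    if (r$all_hit[i]) {
      expect_equal(r$label_shifts[i], 0)
      expect_identical(r$prediction[i], r$label[i])
    }
  }
  rep1 <- metric_report(r)
  expect_true(rep1$accuracy >= 0 && rep1$accuracy <= 100)
  expect_true(rep1$all_hit_ratio >= 0 && rep1$all_hit_ratio <= 100)
  expect_true(all(r$label_shifts <= 15))
})

test_that("offline replay with the online model reproduces the online log", {
  m <- fix_model()
  sess <- fix_eval_session()
  online <- run_session(m, sess, online_protocol(), n_runs = 4,
                        finetune_after = 4, finetune = FALSE)
  rp <- replay_offline(list(online = m), sess, online_protocol())
  expect_identical(rp$results[[1]]$prediction, online$results$prediction)
  expect_equal(rp$accuracy, accuracy_pct(online$results))

  # two models, identical windows: same number of evaluated trials
  set.seed(2)
  m2 <- build_eegnet(eegnet_spec(32, 100, 2))
  m2$classes <- m$classes
  rp2 <- replay_offline(list(a = m, b = m2), sess, online_protocol())
  expect_equal(rp2$n_trials[1], rp2$n_trials[2])

  bad <- build_eegnet(eegnet_spec(16, 100, 2))
  expect_error(replay_offline(list(x = bad), sess), "mismatch")
})
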