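tiny_spec <- function(Z = 3)
  eegnet_spec(4, 32, Z, F1 = 2, D = 2, temporal_kernel_len = 8,
              sep_kernel_len = 4, pool1 = 2, pool2 = 2)

tiny_batch <- function(spec, N = 5, seed = 1) {
  set.seed(seed)
  list(x = array(rnorm(spec$C * spec$T * N), c(spec$C, spec$T, N)),
       y = as.integer(sample(0:(spec$Z - 1), N, TRUE)))
}

test_that("trainable parameter count matches layer-by-layer arithmetic", {
  spec <- eegnet_spec(32, 100, 2)
  set.seed(1)
  m <- build_eegnet(spec)
  # independent hand computation for C=32, T=100, Z=2, F1=8, D=2, F2=16,
  # L=50, Ls=16, pools 4/8 -> T2 = floor(floor(100/4)/8) = 3:
  #   temporal 50*8 = 400, BN 16; depthwise 32*16 = 512, BN 32;
  #   separable 16*16 + 16*16 = 512, BN 32; dense 2*(16*3) + 2 = 98
  expect_equal(m$n_params, 400 + 16 + 512 + 32 + 512 + 32 + 98)
  # the stored parameters really hold that many trainable numbers
  train_names <- setdiff(names(m$par),
                         grep("^(m|v)", names(m$par), value = TRUE))
  expect_equal(sum(lengths(m$par[train_names])), m$n_params)
})

test_that("deep variant has strictly more parameters than standard", {
  std <- eegnet_spec(32, 100, 3)
  dp <- eegnet_spec(32, 100, 3, variant = "deep")
  set.seed(1)
  expect_gt(build_eegnet(dp)$n_params, build_eegnet(std)$n_params)
  expect_equal(dp$F1, 16)
  expect_equal(dp$nblocks, 3)
})

test_that("forward pass returns simplex probabilities, even on zeros", {
  spec <- tiny_spec()
  set.seed(2)
  m <- build_eegnet(spec)
  x0 <- array(0, c(spec$C, spec$T, 3))
  p <- predict_proba(m, x0)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # inference is deterministic: duplicated segment, identical outputs
  xb <- tiny_batch(spec)$x
  p2 <- predict_proba(m, xb[, , c(1, 1)])
  expect_identical(p2[1, ], p2[2, ])

  expect_error(predict_proba(m, array(0, c(2, 2, 1))), "expects")
  expect_error(eegnet_spec(4, 8, 2, pool1 = 4, pool2 = 8), "too short")
})

test_that("analytic gradients match finite differences (training mode)", {
  spec <- tiny_spec()
  set.seed(3)
  m <- build_eegnet(spec)
  b <- tiny_batch(spec, N = 4, seed = 4)
  cspec <- fingerbci:::.cpp_spec(spec)
  out <- fingerbci:::eegnet_pass(m$par, cspec, b$x, b$y, TRUE, FALSE, 0)
  num <- function(nm, i, eps = 1e-6) {
    p1 <- m$par; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- m$par; p2[[nm]][i] <- p2[[nm]][i] - eps
    (fingerbci:::eegnet_pass(p1, cspec, b$x, b$y, TRUE, FALSE, 0)$loss -
       fingerbci:::eegnet_pass(p2, cspec, b$x, b$y, TRUE, FALSE, 0)$loss) /
      (2 * eps)
  }
  set.seed(5)
  for (nm in names(out$grads)) {
    g <- out$grads[[nm]]
    for (i in sample(length(g), min(4, length(g)))) {
      ng <- num(nm, i)
      expect_lt(abs(g[i] - ng) / max(1e-4, abs(g[i]) + abs(ng)), 1e-4)
    }
  }
})

test_that("input gradients match finite differences (saliency path)", {
  spec <- tiny_spec(Z = 2)
  set.seed(6)
  m <- build_eegnet(spec)
  b <- tiny_batch(spec, N = 3, seed = 7)
  cspec <- fingerbci:::.cpp_spec(spec)
  p <- fingerbci:::eegnet_forward_cpp(m$par, cspec, b$x)
  cl <- max.col(t(p))
  G <- fingerbci:::eegnet_input_grad(m$par, cspec, b$x, as.integer(cl) - 1L)
  psum <- function(x) {
    pp <- fingerbci:::eegnet_forward_cpp(m$par, cspec, x)
    sum(pp[cbind(cl, seq_along(cl))])
  }
  set.seed(8)
  for (i in sample(length(b$x), 6)) {
    eps <- 1e-6
    x1 <- b$x; x1[i] <- x1[i] + eps
    x2 <- b$x; x2[i] <- x2[i] - eps
    ng <- (psum(x1) - psum(x2)) / (2 * eps)
    expect_lt(abs(G[i] - ng) / max(1e-4, abs(G[i]) + abs(ng)), 1e-4)
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  cfg <- synth_config(trials_per_class = 6, seed = 21)
  ts <- epoch_trials(preprocess_online(generate_session(cfg)), 0, 3)
  tc <- train_config(max_epochs = 4, patience = 4, lr = 3e-3, seed = 13)
  run <- function() {
    set.seed(99)
    train_eegnet(build_eegnet(eegnet_spec(32, 100, 2)), ts, tc)
  }
  m1 <- run()
  m2 <- run()
  expect_identical(m1$par, m2$par)
  expect_identical(m1$history, m2$history)
})

test_that("training validates class coverage and learns the easy problem", {
  ts <- fix_trialset()
  m <- fix_model()
  expect_gte(max(m$history$val_acc), 0.9)
  expect_false(any(!is.finite(m$history$train_loss)))

  bad <- ts
  bad$labels <- rep("thumb", n_trials(ts))
  set.seed(1)
  expect_error(train_eegnet(build_eegnet(eegnet_spec(32, 100, 2)), bad),
               "class")
})

test_that("fine-tuning freezes the first four layers bit-exactly", {
  m <- fix_model()
  cfg2 <- synth_config(trials_per_class = 6, seed = 31)
  ts2 <- epoch_trials(preprocess_online(generate_session(cfg2)), 0, 3)
  ft <- finetune_eegnet(m, ts2,
                        train_config(max_epochs = 3, patience = 3,
                                     lr = 3e-3, seed = 2))
  frozen <- fingerbci:::.frozen_names
  for (nm in frozen) expect_identical(ft$par[[nm]], m$par[[nm]])
  later <- setdiff(names(m$par), c(frozen, "m30", "v30"))
  expect_false(all(vapply(later, function(nm)
    identical(ft$par[[nm]], m$par[[nm]]), TRUE)))

  set.seed(1)
  fresh <- build_eegnet(eegnet_spec(32, 100, 2))
  expect_error(finetune_eegnet(fresh, ts2), "trained base model")
  empty <- fingerbci:::ts_subset(ts2, integer())
  expect_error(finetune_eegnet(m, empty), "empty")
})

test_that("saliency chain rule: spatial weights decide channel support", {
  spec <- tiny_spec(Z = 2)
  set.seed(10)
  m <- build_eegnet(spec)
  # hand-constrain the depthwise spatial filters to channels 1 and 3
  m$par$Wdw[c(2, 4), ] <- 0
  b <- tiny_batch(spec, N = 6, seed = 11)
  sm <- saliency_map(m, b$x)
  expect_equal(sm$raw[c(2, 4)], c(0, 0), tolerance = 1e-12)
  expect_true(all(sm$raw[c(1, 3)] > 0))
  expect_true(all(stats::na.omit(sm$saliency) <= 1 + 1e-12))
  expect_equal(max(sm$raw), 1)

  # duplicated batch leaves the map unchanged
  sm2 <- saliency_map(m, b$x[, , c(1:6, 1:6)])
  expect_equal(sm2$raw, sm$raw, tolerance = 1e-12)
  expect_error(saliency_map(m, array(0, c(spec$C, spec$T, 0))), "empty")
})
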