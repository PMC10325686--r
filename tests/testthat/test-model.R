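test_that("default network matches the reference architecture exactly", {
  model <- build_model(arch_config(), seed = 1)
  # four convolution stages with filters (32, 64, 96, 96), 3x3 kernels
  filters <- vapply(1:4, function(s) nrow(model$params[[paste0("Wc", s)]]), 0L)
  expect_equal(filters, c(32L, 64L, 96L, 96L))
  in_ch <- vapply(1:4, function(s)
    ncol(model$params[[paste0("Wc", s)]]) / 9L, 0)
  expect_equal(in_ch, c(1, 32, 64, 96))
  # three fully-connected layers of widths (256, 64, 1)
  fc <- vapply(1:3, function(s) nrow(model$params[[paste0("Wf", s)]]), 0L)
  expect_equal(fc, c(256L, 64L, 1L))
  # each conv stage carries a batch-norm scale/shift pair
  expect_true(all(paste0("gamma", 1:4) %in% names(model$params)))
})

test_that("parameter count is stable across rebuilds", {
  # conv 157,248 + batch-norm 576 + fully-connected 631,169
  expect_equal(n_params(build_model(seed = 1)), 788993L)
  expect_equal(n_params(build_model(seed = 99)), 788993L)
})

test_that("scores are sigmoid outputs: strictly in (0,1), 0.5 at zero logits", {
  model <- build_model(seed = 3)
  x <- list(toy_patch(TRUE), toy_patch(FALSE))
  pr <- predict_cnn(model, x)
  expect_true(all(pr > 0 & pr < 1))
  model$params$Wf3[] <- 0
  model$params$bf3[] <- 0
  expect_equal(predict_cnn(model, x), c(0.5, 0.5))
})

test_that("prediction is deterministic and duplicates score identically", {
  model <- build_model(seed = 5)
  p <- toy_patch(TRUE)
  q <- toy_patch(FALSE)
  pr <- predict_cnn(model, list(p, q, p))
  expect_identical(pr[1], pr[3])
  expect_identical(pr, predict_cnn(model, list(p, q, p)))
  expect_error(predict_cnn(model, list(matrix(0, 10, 10))), "shape mismatch")
})

test_that("analytic gradients agree with finite differences", {
  arch <- small_arch()
  model <- build_model(arch, seed = 2)
  set.seed(3)
  X <- array(stats::rnorm(20 * 20 * 5), c(20, 20, 5))
  y <- c(1, 0, 1, 1, 0)
  st <- cnn_train_step_cpp(model$params, X, y, 0.01, 0)
  for (nm in c("Wc1", "Wc3", "gamma2", "beta4", "Wf1", "Wf3", "bf2")) {
    for (probe in 1:2) {
      i <- sample(length(model$params[[nm]]), 1)
      eps <- 1e-6
      up <- model$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- model$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      gnum <- (cnn_train_step_cpp(up, X, y, 0.01, 0)$loss -
                 cnn_train_step_cpp(dn, X, y, 0.01, 0)$loss) / (2 * eps)
      gana <- st$grads[[nm]][i]
      expect_lt(abs(gnum - gana) / max(1e-6, abs(gnum) + abs(gana)), 1e-3)
    }
  }
})

test_that("plateau scheduler reduces by exactly 0.2 and stops below 1e-7", {
  # 7 epochs of non-decreasing validation loss: reduce
  res <- lr_step(c(1, 1, 1, 1, 1, 1, 1), 1e-3)
  expect_equal(res$next_lr, 2e-4)
  expect_false(res$stop)
  # strictly decreasing: no change
  res2 <- lr_step(c(0.9, 0.8, 0.7), 1e-3)
  expect_equal(res2$next_lr, 1e-3)
  # six consecutive reductions from 1e-3 cross the 1e-7 floor
  lr <- 1e-3
  for (i in 1:6) {
    out <- lr_step(rep(0.5, 7), lr)
    expect_equal(out$next_lr, lr * 0.2)
    lr <- out$next_lr
  }
  expect_equal(lr, 1e-3 * 0.2^6)
  expect_true(out$stop)
})

test_that("short training runs respect epoch limits and are reproducible", {
  set.seed(1)
  xs <- lapply(1:8, function(i) toy_patch(i <= 4))
  ys <- rep(c(1, 0), each = 4)
  cfg <- train_config(epochs_max = 2L, seed = 9L)
  fit1 <- train_cnn(xs, ys, xs[c(1, 8)], ys[c(1, 8)], cfg = cfg)
  expect_equal(nrow(fit1$history), 2L)
  expect_equal(fit1$stop_reason, "epochs_exhausted")
  expect_true(all(diff(fit1$history$lr) <= 0))
  fit2 <- train_cnn(xs, ys, xs[c(1, 8)], ys[c(1, 8)], cfg = cfg)
  expect_identical(fit1$history$train_loss[1], fit2$history$train_loss[1])
  expect_identical(fit1$model$params, fit2$model$params)
  expect_error(train_cnn(list(), numeric(0), xs, ys), "non-empty|patches")
})

test_that("the network memorizes a small separable patch set", {
  set.seed(2)
  xs <- lapply(1:32, function(i) toy_patch(i <= 16))
  ys <- rep(c(1, 0), each = 16)
  fit <- train_cnn(xs, ys, xs[c(1:2, 31:32)], ys[c(1:2, 31:32)],
                   cfg = train_config(epochs_max = 10L, seed = 4L))
  pr <- predict_cnn(fit$model, xs)
  expect_equal(mean((pr > 0.5) == (ys == 1)), 1)
  # descent: later training loss below the first epoch's
  expect_lt(fit$history$train_loss[10], fit$history$train_loss[1])
})
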