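# tiny deterministic 2-class toy problem: dark vs bright 8x8 patches
toy_data <- function(n_per_class, seed, sz = 8L) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(0, dim = c(sz, sz, 3L, n))
  y <- rep(1:2, each = n_per_class)
  for (i in seq_len(n)) {
    base <- if (y[i] == 1) 0.2 else 0.8
    x[, , , i] <- pmin(pmax(base + rnorm(sz * sz * 3, 0, 0.05), 0), 1)
  }
  list(x = x, y = y)
}

tiny_model <- function(n_classes = 2L, seed = 1L)
  small_cnn(input_size = 8, filters = c(3L, 4L), n_classes = n_classes,
            seed = seed)

test_that("mean loss is the arithmetic mean of per-sample losses", {
  expect_equal(mean_loss(rep(0, 5)), 0)
  expect_equal(mean_loss(c(0.5, 1.5)), 1)
  set.seed(3)
  v <- runif(100, 0, 4)
  oracle <- 0
  for (l in v) oracle <- oracle + l
  expect_lt(abs(mean_loss(v) - oracle / 100), 1e-12)
  expect_error(mean_loss(numeric(0)), "empty")
  expect_error(mean_loss(c(0.1, -0.2)), "nonnegative")
})

test_that("swap_head preserves the backbone and reseeds the head", {
  m <- tiny_model(n_classes = 3L, seed = 7)
  ck <- histostep:::weight_checksum(m$backbone)
  m2 <- swap_head(m, 2L, seed = 42)
  expect_identical(m2$backbone, m$backbone)
  expect_identical(histostep:::weight_checksum(m2$backbone), ck)
  expect_equal(nrow(m2$head$W), 2L)
  expect_equal(m2$arch$n_classes, 2L)
  # same class count: explicitly not a no-op
  m3 <- swap_head(m, 3L, seed = 42)
  expect_false(isTRUE(all.equal(m3$head$W, m$head$W)))
  # same seed twice -> identical head
  expect_identical(swap_head(m, 2L, seed = 42)$head, m2$head)
  expect_error(swap_head(m, 1L), ">= 2")
})

test_that("analytic gradients match finite differences", {
  set.seed(11)
  model <- small_cnn(input_size = 8, in_channels = 2, filters = c(2L, 3L),
                     n_classes = 3L, seed = 2)
  x <- array(runif(8 * 8 * 2 * 4), c(8, 8, 2, 4))
  y <- c(1L, 2L, 3L, 1L)
  lg <- histostep:::nn_loss_grad(model, x, y)
  lossfun <- function(m) mean(histostep:::nn_loss_grad(m, x, y)$losses)
  eps <- 1e-5
  check <- function(get, set, g) {
    ks <- sample(length(g), min(6, length(g)))
    for (k in ks) {
      m1 <- set(model, k, eps); m2 <- set(model, k, -eps)
      num <- (lossfun(m1) - lossfun(m2)) / (2 * eps)
      expect_lt(abs(num - g[k]), 1e-6)
    }
  }
  check(NULL, function(m, k, e) { m$head$W[k] <- m$head$W[k] + e; m },
        lg$grads$head$W)
  check(NULL, function(m, k, e) { m$head$b[k] <- m$head$b[k] + e; m },
        lg$grads$head$b)
  for (li in 1:2) {
    check(NULL, function(m, k, e) {
      m$backbone[[li]]$W[k] <- m$backbone[[li]]$W[k] + e; m
    }, lg$grads$backbone[[li]]$W)
    check(NULL, function(m, k, e) {
      m$backbone[[li]]$b[k] <- m$backbone[[li]]$b[k] + e; m
    }, lg$grads$backbone[[li]]$b)
  }
})

test_that("run_stage trains, selects on validation, and is deterministic", {
  train <- toy_data(16, seed = 21)
  val <- toy_data(8, seed = 22)
  st <- training_stage(train$x, train$y, val$x, val$y, n_classes = 2L,
                       epochs = 20L, seed = 5L, name = "toy")
  model <- tiny_model(seed = 9)
  res <- run_stage(model, st)
  expect_lt(res$log$train_loss[20], res$log$train_loss[1])
  expect_equal(nrow(res$log), 20L)
  expect_true(all(is.finite(res$log$train_loss)))
  # deterministic under identical seed/data/config
  res2 <- run_stage(model, st)
  expect_identical(res$log, res2$log)
  expect_identical(res$model, res2$model)
  # 0 epochs: unchanged model, empty log
  st0 <- training_stage(train$x, train$y, val$x, val$y, 2L, epochs = 0L)
  r0 <- run_stage(model, st0)
  expect_identical(r0$model, model)
  expect_equal(nrow(r0$log), 0L)
  # non-finite weights abort with a stage diagnostic
  broken <- model; broken$head$W[1] <- NaN
  expect_error(run_stage(broken, st), "non-finite loss.*toy")
})

test_that("run_stepwise executes schedules with the stated head-swap logic", {
  train <- toy_data(12, seed = 31); val <- toy_data(6, seed = 32)
  med <- training_stage(train$x, train$y, val$x, val$y, n_classes = 3L,
                        epochs = 2L, seed = 3L, name = "medium")
  high <- training_stage(train$x, train$y, val$x, val$y, n_classes = 2L,
                         epochs = 2L, seed = 4L, name = "high")
  # 3-class medium then 2-class high: exactly one swap, two stage blocks
  two <- run_stepwise(stage_schedule(list(med, high), init_seed = 1L,
                                     input_size = 8L, filters = c(3L, 4L)))
  expect_equal(two$head_swaps, 1L)
  expect_equal(unique(two$log$stage), c("medium", "high"))
  expect_equal(two$model$arch$n_classes, 2L)
  # a one-stage schedule is the plain baseline: same result as manual init +
  # run_stage with the same seeds
  one <- run_stepwise(stage_schedule(list(high), init_seed = 1L,
                                     input_size = 8L, filters = c(3L, 4L)))
  manual_model <- small_cnn(input_size = 8, filters = c(3L, 4L),
                            n_classes = 2L, seed = 1L)
  manual <- run_stage(manual_model, high)
  expect_identical(one$model, manual$model)
  expect_identical(one$log, manual$log)
  expect_equal(one$head_swaps, 0L)
  expect_error(stage_schedule(list()), "1 \\(baseline\\) or 2")
  expect_error(stage_schedule(list(med, high, med)), "1 \\(baseline\\) or 2")
})

test_that("training the toy problem reaches a useful validation AUC", {
  train <- toy_data(16, seed = 41); val <- toy_data(10, seed = 42)
  st <- training_stage(train$x, train$y, val$x, val$y, 2L, epochs = 15L,
                       seed = 6L)
  res <- run_stage(tiny_model(seed = 10), st)
  expect_gt(res$log$val_auc[nrow(res$log)], 0.9)
})
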