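test_that("tanh activation: odd, bounded, saturating", {
  expect_equal(tanh_activation(0), 0)
  for (x in c(0.5, 1, 2))
    expect_equal(tanh_activation(-x), -tanh_activation(x))
  expect_equal(tanh_activation(20), 1, tolerance = 1e-9)
  expect_true(all(abs(tanh_activation(seq(-10, 10, 0.5))) < 1))
})

test_that("min-max scaling round-trips and handles degenerate ranges", {
  set.seed(61)
  X <- matrix(rnorm(40, 5, 3), 10, 4)
  sc <- ct2bmd:::fit_minmax(X)
  Z <- ct2bmd:::apply_minmax(X, sc)
  expect_true(all(Z >= -1 & Z <= 1))
  expect_equal(ct2bmd:::invert_minmax(Z, sc), X, tolerance = 1e-12)
  Xc <- cbind(X[, 1], 7)  # constant column
  scc <- ct2bmd:::fit_minmax(Xc)
  Zc <- ct2bmd:::apply_minmax(Xc, scc)
  expect_true(all(Zc[, 2] == 0))
  expect_equal(ct2bmd:::invert_minmax(Zc, scc)[, 2], rep(7, 10))
})

test_that("forward pass matches hand evaluation on reduced networks", {
  # zero network: output is the (inverse-scaled) output bias
  net <- init_network(seed = 1, n_in = 5, n_hidden = 40)
  net$W1[] <- 0; net$W2[] <- 0; net$b2 <- 0.25
  net$target_scaling <- list(min = 0, max = 2)  # 0.25 -> 1.25
  x <- matrix(runif(5), 1, 5)
  expect_equal(unname(predict(net, x)), 1.25, tolerance = 1e-12)

  # 1-hidden-neuron net, identity scalings: y = tanh(x1)
  n1 <- init_network(seed = 1, n_in = 5, n_hidden = 1)
  n1$W1 <- matrix(c(1, 0, 0, 0, 0), 1, 5)
  n1$b1 <- 0; n1$W2 <- matrix(1, 1, 1); n1$b2 <- 0
  inp <- matrix(c(0.5, 9, 9, 9, 9), 1, 5)
  expect_equal(unname(predict(n1, inp)), tanh(0.5), tolerance = 1e-12)

  expect_error(predict(net, matrix(c(NA, 1, 1, 1, 1), 1, 5)),
               class = "ct2bmd_input_error")
})

test_that("one gradient step on a 1-neuron net matches the hand chain rule", {
  net <- init_network(seed = 2, n_in = 1, n_hidden = 1)
  w1 <- 0.3; b1 <- 0.1; w2 <- 0.7; b2 <- -0.2
  net$W1 <- matrix(w1); net$b1 <- b1; net$W2 <- matrix(w2); net$b2 <- b2
  s <- 0.4; t <- 0.9
  g <- nn_gradient(net, matrix(s), t)
  h <- tanh(w1 * s + b1)
  y <- w2 * h + b2
  e <- 2 * (y - t)                 # d(mse)/dy, n = 1
  expect_equal(g$b2, e, tolerance = 1e-9)
  expect_equal(as.numeric(g$W2), e * h, tolerance = 1e-9)
  expect_equal(g$b1, e * w2 * (1 - h^2), tolerance = 1e-9)
  expect_equal(as.numeric(g$W1), e * w2 * (1 - h^2) * s, tolerance = 1e-9)
  expect_equal(g$mse, (y - t)^2, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences (5-40-1)", {
  # the core correctness gate, over multiple random nets and batches
  for (seed in 1:20) {
    set.seed(seed + 1000)
    net <- init_network(seed, n_in = 5, n_hidden = 40)
    net$b1 <- rnorm(40, 0, 0.1); net$b2 <- rnorm(1, 0, 0.1)
    S <- matrix(runif(5 * 7, -1, 1), 5, 7)
    tt <- runif(7, -1, 1)
    g <- nn_gradient(net, S, tt)
    # probe a random subset of each parameter block
    for (k in 1:4) {
      i <- sample(40, 1); j <- sample(5, 1)
      fd <- fd_gradient(net, S, tt, "W1", i, j)
      expect_equal(g$W1[i, j], fd, tolerance = 1e-6)
      i2 <- sample(40, 1)
      expect_equal(g$b1[i2], fd_gradient(net, S, tt, "b1", i2), tolerance = 1e-6)
      expect_equal(g$W2[1, i2], fd_gradient(net, S, tt, "W2", 1, i2), tolerance = 1e-6)
    }
    expect_equal(g$b2, fd_gradient(net, S, tt, "b2", 1), tolerance = 1e-6)
  }
})

test_that("split_dataset: sizes, determinism, partition property", {
  sp <- split_dataset(20, seed = 3)
  expect_equal(lengths(sp), c(train = 14L, val = 3L, test = 3L))
  sp2 <- split_dataset(20, seed = 3)
  expect_identical(sp, sp2)
  expect_setequal(unlist(sp), 1:20)
  expect_equal(anyDuplicated(unlist(sp)), 0)
  sp9 <- split_dataset(9, fractions = c(7, 1, 1) / 9, seed = 1)
  expect_equal(lengths(sp9), c(train = 7L, val = 1L, test = 1L))
  expect_error(split_dataset(2), class = "ct2bmd_size_error")
})

test_that("training is deterministic and monotone at small learning rates", {
  set.seed(71)
  X <- matrix(runif(60 * 5), 60, 5)
  y <- X %*% c(1, -2, 0.5, 0, 1) + 0.1
  cfg <- training_config(learning_rate = 0.01, max_epochs = 10,
                         val_patience = Inf, seed = 5)
  f1 <- train_bmd_network(X, y, cfg)
  f2 <- train_bmd_network(X, y, cfg)
  expect_identical(f1$network$W1, f2$network$W1)
  expect_identical(f1$network$b2, f2$network$b2)
  expect_true(all(diff(f1$record$epochs$train_mse) <= 0))
})

test_that("a representable function is learned to low MSE", {
  set.seed(72)
  X <- matrix(runif(80 * 5, -1, 1), 80, 5)
  y <- 0.8 * X[, 2] + 0.1   # exact linear function of one feature
  cfg <- training_config(max_epochs = 2000, val_patience = Inf, seed = 6)
  fit <- train_bmd_network(X, y, cfg)
  tr <- fit$split$train
  pred <- predict(fit$network, X)
  expect_lt(mse(pred[tr], y[tr]), 1e-3)
})

test_that("early stopping restores best-validation weights", {
  set.seed(73)
  X <- matrix(runif(40 * 5), 40, 5)
  y <- rnorm(40)  # pure noise: validation will stop improving quickly
  cfg <- training_config(max_epochs = 500, val_patience = 6, seed = 7)
  fit <- train_bmd_network(X, y, cfg)
  rec <- fit$record
  if (rec$stop_reason == "early_stopping") {
    expect_lte(nrow(rec$epochs), 500)
    expect_lte(rec$best_epoch, nrow(rec$epochs))
    # restored weights reproduce the best epoch's validation MSE
    va <- fit$split$val
    pred_s <- ct2bmd:::nn_forward_scaled(
      fit$network,
      t(ct2bmd:::apply_minmax(X[va, , drop = FALSE], fit$network$input_scaling)))$Y
    tgt_s <- drop(ct2bmd:::apply_minmax(matrix(y[va]), fit$network$target_scaling))
    expect_equal(mean((pred_s - tgt_s)^2), min(rec$epochs$val_mse),
                 tolerance = 1e-12)
  }
  expect_true(all(is.finite(rec$epochs$train_mse)))
})

test_that("training errors: divergence, constant targets, bad sizes", {
  set.seed(74)
  X <- matrix(runif(30 * 5, 0, 1), 30, 5)
  y <- runif(30)
  expect_error(
    train_bmd_network(X, y, training_config(learning_rate = 1e4,
                                            max_epochs = 500,
                                            val_patience = Inf, seed = 1)),
    class = "ct2bmd_training_diverged_error")
  expect_error(train_bmd_network(X, rep(1, 30), training_config(seed = 1)),
               class = "ct2bmd_degenerate_error")
  expect_error(train_bmd_network(X, y[1:10], training_config(seed = 1)),
               class = "ct2bmd_size_error")
})

test_that("parameter recovery: data from a known 5-40-1 net is refit to R >= 0.99", {
  set.seed(80)
  teacher <- init_network(seed = 80, n_in = 5, n_hidden = 40)
  n <- 400
  X <- matrix(runif(n * 5, -1, 1), n, 5)
  y_clean <- drop(teacher$W2 %*% tanh(teacher$W1 %*% t(X) + teacher$b1)) + teacher$b2
  y <- y_clean + rnorm(n, 0, 0.01 * sd(y_clean))
  cfg <- training_config(max_epochs = 3000, seed = 81)
  fit <- train_bmd_network(X, y, cfg)
  te <- fit$split$test
  r_heldout <- correlation_coefficient(predict(fit$network, X[te, ]), y[te])
  expect_gte(r_heldout, 0.99)
})

test_that("metrics: mse and Pearson R behave per contract", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  a <- runif(10); b <- runif(10)
  expect_equal(mse(a, b), mse(b, a))
  expect_error(mse(1:3, 1:4), class = "ct2bmd_size_error")
  x <- c(1, 2, 3)
  expect_equal(correlation_coefficient(x, x), 1)
  expect_equal(correlation_coefficient(x, -x), -1)
  expect_equal(correlation_coefficient(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_error(correlation_coefficient(c(1, 1, 1), x),
               class = "ct2bmd_degenerate_error")
})

test_that("model JSON round-trip predicts identically", {
  set.seed(90)
  X <- matrix(runif(50 * 5), 50, 5)
  y <- X %*% runif(5) + 0.2
  fit <- train_bmd_network(X, y, training_config(max_epochs = 50, seed = 9))
  p <- withr::local_tempfile(fileext = ".json")
  write_bmd_network(fit$network, p)
  back <- read_bmd_network(p)
  expect_equal(predict(back, X), predict(fit$network, X), tolerance = 1e-12)
  expect_identical(back$rng_seed, fit$network$rng_seed)
})
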