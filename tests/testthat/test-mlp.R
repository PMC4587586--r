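test_that("initialization is seeded, shaped, and validated", {
  cfg <- mlp_config(3, 2, "lm", seed = 11)
  m1 <- mlp_init(cfg); m2 <- mlp_init(cfg)
  expect_identical(m1$theta, m2$theta)
  # 2x3 hidden weights + 2 hidden biases + 2 output weights + 1 output bias
  expect_length(m1$theta, 6 + 2 + 2 + 1)
  w <- resicast:::unpack_theta(m1$theta, cfg)
  expect_equal(dim(w$W1), c(2L, 3L))
  expect_error(mlp_config(3, 0), "n_hidden")
  expect_error(mlp_config(3, 25), "n_hidden")
  expect_error(mlp_config(0, 2), "lags")
})

test_that("forward pass matches hand computation and is deterministic", {
  cfg <- mlp_config(1, 1, "lm", seed = 1)
  m <- mlp_init(cfg)
  m$theta <- c(0.7, 0.1, 1.3, -0.2)  # W1, b1, w2, b2
  x <- matrix(c(0.4, 0.9), ncol = 1)
  h <- 1 / (1 + exp(-(0.7 * x + 0.1)))
  expect_equal(mlp_forward(m, x), as.numeric(1.3 * h - 0.2), tolerance = 1e-12)
  # zero weights: every prediction equals the output bias
  m$theta <- c(0, 0, 0, 0.37)
  expect_equal(mlp_forward(m, x), c(0.37, 0.37), tolerance = 1e-12)
  # duplicate rows give duplicate outputs
  m2 <- mlp_init(mlp_config(2, 3, "scg", seed = 4))
  X <- matrix(runif(8), ncol = 2)[c(1, 1, 2, 3), ]
  out <- mlp_forward(m2, X)
  expect_identical(out[1], out[2])
  expect_error(mlp_forward(m2, matrix(1, 1, 3)), "width")
})

test_that("analytic gradient matches finite differences", {
  set.seed(12)
  cfg <- mlp_config(2, 3, "lm", seed = 2)
  m <- mlp_init(cfg)
  X <- matrix(runif(20), ncol = 2); y <- runif(10)
  g <- resicast:::net_grad(m$theta, X, y, cfg)
  num <- vapply(seq_along(m$theta), function(i) {
    h <- 1e-6
    tp <- m$theta; tp[i] <- tp[i] + h
    tm <- m$theta; tm[i] <- tm[i] - h
    (resicast:::net_mse(tp, X, y, cfg) - resicast:::net_mse(tm, X, y, cfg)) / (2 * h)
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("all four trainers fit a constant target to near zero error", {
  x <- rep(0.6, 60)
  sets <- resicast:::supervised_sets(x[1:40], x[41:60], 2)
  for (tr in c("lm", "scg", "rprop", "oss")) {
    m <- mlp_train(mlp_init(mlp_config(2, 2, tr, seed = 3)),
                   sets$train, sets$val, train_options(max_iterations = 200))
    expect_lt(min(m$training_log$train_mse), 1e-4)
  }
})

test_that("trainers reduce training error and return the best-val snapshot", {
  b <- gen_ar(500, 0.8, seed = 42)
  sp <- chronological_split(b, split_spec(0.8, 0.1, 0.1))
  sets <- resicast:::supervised_sets(sp$train$values, sp$val$values, 1)
  for (tr in c("lm", "scg", "rprop", "oss")) {
    m0 <- mlp_init(mlp_config(1, 2, tr, seed = 7))
    m <- mlp_train(m0, sets$train, sets$val, train_options(max_iterations = 300))
    log <- m$training_log
    e_tr_final <- resicast:::net_mse(m$theta, sets$train$inputs,
                                     sets$train$targets, m$config)
    expect_lte(e_tr_final, log$train_mse[1] + 1e-12)
    # early stopping: returned weights realize the minimum logged val error
    e_va_final <- resicast:::net_mse(m$theta, sets$val$inputs,
                                     sets$val$targets, m$config)
    expect_equal(e_va_final, min(log$val_mse), tolerance = 1e-12)
    # AR(1) phi=0.8, innovation variance 1: near-optimal one-step forecasts
    expect_lte(e_va_final, 1.2)
  }
})

test_that("seeded training runs are exactly reproducible", {
  b <- gen_ar(200, 0.7, seed = 5)
  sets <- resicast:::supervised_sets(b$values[1:150], b$values[151:200], 2)
  run <- function() mlp_train(mlp_init(mlp_config(2, 3, "rprop", seed = 9)),
                              sets$train, sets$val,
                              train_options(max_iterations = 100))
  m1 <- run(); m2 <- run()
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$training_log, m2$training_log)
})

test_that("models serialize to JSON-compatible lists and back", {
  b <- gen_ar(150, 0.6, seed = 8)
  sets <- resicast:::supervised_sets(b$values[1:110], b$values[111:150], 2)
  m <- mlp_train(mlp_init(mlp_config(2, 2, "lm", seed = 1)),
                 sets$train, sets$val, train_options(max_iterations = 50))
  l <- resicast:::model_to_list(m)
  m2 <- resicast:::model_from_list(l)
  X <- matrix(runif(10), ncol = 2)
  expect_identical(mlp_forward(m, X), mlp_forward(m2, X))
})
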