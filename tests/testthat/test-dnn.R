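# The feedforward LogP regression network.

test_that("the default architecture has the pinned parameter counts", {
  m <- build_model(model_spec(), seed = 1)
  # hidden + output stack: 319*256+256 + 256*164+164 + 164*10+10 + 10*1+1
  expect_equal(n_parameters(m, include_input_layer = FALSE), 125729)
  # plus the trainable sigmoid input layer: 319*319 + 319
  expect_equal(n_parameters(m), 125729 + 319 * 319 + 319)
  # first hidden layer shape
  expect_equal(dim(m$weights[[2]]$W), c(319L, 256L))
})

test_that("initialization is seed-reproducible and the forward pass is finite", {
  a <- build_model(model_spec(), seed = 99)
  b <- build_model(model_spec(), seed = 99)
  expect_identical(a$weights, b$weights)
  c <- build_model(model_spec(), seed = 100)
  expect_false(identical(a$weights, c$weights))
  out <- predict_logp(a, matrix(0, 1, 319))
  expect_true(is.finite(out))
})

test_that("invalid specs are rejected", {
  expect_error(model_spec(input_width = 0), "positive")
  expect_error(model_spec(hidden_widths = c(8, 4),
                          hidden_activations = "tanh"), "equal length")
  expect_error(training_config(epochs = 0))
})

test_that("analytic gradients match finite differences to 1e-4", {
  spec <- model_spec(input_width = 10L, hidden_widths = c(7L, 5L, 3L))
  m <- build_model(spec, seed = 42)
  set.seed(7)
  X <- matrix(rnorm(50), 5, 10)
  y <- rnorm(5)
  g <- fraglogp:::fl_gradients(m, X, y)
  loss_at <- function(mm) mean((fraglogp:::fl_forward(mm, X) - y)^2)
  eps <- 1e-6
  worst <- 0
  for (l in seq_along(m$weights)) {
    for (i in seq_along(m$weights[[l]]$W)) {
      m2 <- m; m2$weights[[l]]$W[i] <- m2$weights[[l]]$W[i] + eps
      m3 <- m; m3$weights[[l]]$W[i] <- m3$weights[[l]]$W[i] - eps
      num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      worst <- max(worst, abs(num - g$grads[[l]]$W[i]) / max(abs(num), 1e-8))
    }
    for (i in seq_along(m$weights[[l]]$b)) {
      m2 <- m; m2$weights[[l]]$b[i] <- m2$weights[[l]]$b[i] + eps
      m3 <- m; m3$weights[[l]]$b[i] <- m3$weights[[l]]$b[i] - eps
      num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      worst <- max(worst, abs(num - g$grads[[l]]$b[i]) / max(abs(num), 1e-8))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("a constant-target dataset is fit to the constant", {
  sim <- generate_regression_set(200, n_features = 20, k = 5, noise_sd = 0,
                                 seed = 5)
  y <- rep(2.0, 200)
  m <- build_model(model_spec(input_width = 20L,
                              hidden_widths = c(16L, 8L, 4L)), seed = 5)
  m <- train_model(m, sim$features, y,
                   config = training_config(epochs = 78, seed = 5))
  expect_lt(tail(m$history$train_rmse, 1), 0.05)
  preds <- predict_logp(m, sim$features)
  expect_true(all(abs(preds - 2.0) < 0.1))
})

test_that("training reduces RMSE on a noiseless linear problem (3 seeds)", {
  for (seed in 1:3) {
    sim <- generate_regression_set(500, n_features = 30, k = 8, noise_sd = 0,
                                   seed = seed)
    m <- build_model(model_spec(input_width = 30L,
                                hidden_widths = c(32L, 16L, 4L)), seed = seed)
    m <- train_model(m, sim$features, sim$targets,
                     config = training_config(epochs = 78, seed = seed))
    expect_lt(m$history$train_rmse[78], m$history$train_rmse[1])
  }
})

test_that("training history covers every epoch and both splits", {
  sim <- generate_regression_set(120, n_features = 12, k = 4, seed = 2)
  m <- build_model(model_spec(input_width = 12L,
                              hidden_widths = c(8L, 6L, 3L)), seed = 2)
  m <- train_model(m, sim$features[1:80, ], sim$targets[1:80],
                   sim$features[81:120, ], sim$targets[81:120],
                   training_config(epochs = 9, seed = 2))
  expect_equal(nrow(m$history), 9L)
  expect_true(all(is.finite(m$history$train_rmse)))
  expect_true(all(is.finite(m$history$valid_rmse)))
})

test_that("identical seeds give bit-identical trained weights", {
  sim <- generate_regression_set(100, n_features = 10, k = 3, seed = 8)
  run <- function() {
    m <- build_model(model_spec(input_width = 10L,
                                hidden_widths = c(8L, 4L, 2L)), seed = 8)
    train_model(m, sim$features, sim$targets,
                config = training_config(epochs = 5, seed = 8))
  }
  expect_identical(run()$weights, run()$weights)
})

test_that("prediction is row-equivariant and rejects width mismatches", {
  m <- build_model(model_spec(input_width = 6L,
                              hidden_widths = c(5L, 4L, 2L)), seed = 3)
  X <- matrix(rnorm(60), 10, 6)
  p <- predict_logp(m, X)
  expect_length(p, 10L)
  perm <- sample(10)
  expect_equal(predict_logp(m, X[perm, ]), p[perm])
  expect_error(predict_logp(m, matrix(0, 2, 7)), "width")
  expect_error(train_model(m, matrix(0, 4, 7), rep(0, 4)), "width")
})

test_that("divergent training aborts with a learning-rate diagnostic", {
  sim <- generate_regression_set(64, n_features = 8, k = 3, seed = 4)
  m <- build_model(model_spec(input_width = 8L,
                              hidden_widths = c(6L, 4L, 2L)), seed = 4)
  expect_error(
    train_model(m, sim$features, sim$targets * 1e160,
                config = training_config(learning_rate = 1e8, epochs = 3,
                                         seed = 4)),
    "learning rate")
})

test_that("save/load round-trips to bit-identical predictions", {
  sim <- generate_regression_set(80, n_features = 9, k = 3, seed = 6)
  m <- build_model(model_spec(input_width = 9L,
                              hidden_widths = c(7L, 5L, 2L)), seed = 6)
  m <- train_model(m, sim$features, sim$targets,
                   config = training_config(epochs = 4, seed = 6))
  arch <- withr::local_tempfile(fileext = ".json")
  weights <- withr::local_tempfile(fileext = ".bin")
  save_model(m, arch, weights)
  expect_true(file.exists(arch) && file.exists(weights))
  expect_false(identical(readBin(arch, "raw", 100),
                         readBin(weights, "raw", 100)))
  m2 <- load_model(arch, weights)
  X <- sim$features[1:10, ]
  expect_identical(predict_logp(m, X), predict_logp(m2, X))
  expect_equal(nrow(m2$history), 4L)

  # weights from a different architecture are rejected
  other <- build_model(model_spec(input_width = 9L,
                                  hidden_widths = c(3L, 2L, 2L)), seed = 1)
  weights2 <- withr::local_tempfile(fileext = ".bin")
  saveRDS(other$weights, weights2)
  expect_error(load_model(arch, weights2), "does not match")
  expect_error(load_model(file.path(tempdir(), "missing.json"), weights),
               "not found")
})
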