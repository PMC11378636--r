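make_toy_encoder <- function(seed = 1) {
  sp <- autoencoder_spec(20L, 8L, 4L)
  X <- {
    set.seed(seed)
    matrix(rnorm(30 * 20), 30, 20, dimnames = list(paste0("S", 1:30),
                                                   paste0("G", 1:20)))
  }
  ae <- train_autoencoder(X, sp, config = train_config(epochs = 2, seed = seed))
  extract_encoder(ae, "target_only", selected_genes = paste0("G", 1:20))
}

test_that("the head plugs into the bottleneck and keeps encoder weights", {
  enc <- make_toy_encoder()
  model <- build_predictor(enc, "regression", head_config = list(hidden = c(6, 3),
                                                                 seed = 2))
  expect_equal(nrow(model$net$layers[[3]]$W), 4L)  # head input == bottleneck
  expect_identical(model$net$layers[1:2], enc$layers)
  man <- tidy(model)
  expect_equal(man$activation, c("lrelu", "lrelu", "relu", "relu", "identity"))
})

test_that("zero-epoch fine-tuning is a strict no-op", {
  enc <- make_toy_encoder(3)
  model <- build_predictor(enc, "regression", head_config = list(seed = 4))
  set.seed(5)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- rnorm(40)
  fitted <- fit_predictor(model, X, y, config = train_config(epochs = 0, seed = 6))
  expect_identical(fitted$net$layers, model$net$layers)
  expect_identical(predict(fitted, X), predict(model, X))
})

test_that("fine-tuning a latent-driven target beats the intercept-only baseline", {
  set.seed(8)
  n <- 200; d <- 3
  Z <- matrix(rnorm(n * d), n, d)
  X <- Z %*% matrix(rnorm(d * 20), d, 20) + matrix(rnorm(n * 20, sd = 0.3), n, 20)
  colnames(X) <- paste0("G", 1:20)
  y <- Z %*% c(2, -1, 0.5) + rnorm(n, sd = 0.2)
  sp <- autoencoder_spec(20L, 8L, 4L)
  ae <- train_autoencoder(X, sp, config = train_config(epochs = 30, seed = 9))
  enc <- extract_encoder(ae, "target_only")
  model <- build_predictor(enc, "regression", head_config = list(hidden = c(16, 8),
                                                                 seed = 10))
  fitted <- fit_predictor(model, X, as.numeric(y),
                          config = train_config(epochs = 60, seed = 11))
  expect_lt(mse(as.numeric(y), predict(fitted, X)), var(as.numeric(y)))
})

test_that("the freeze flag pins encoder weights while the head trains", {
  enc <- make_toy_encoder(12)
  model <- build_predictor(enc, "regression", head_config = list(seed = 13))
  set.seed(14)
  X <- matrix(rnorm(50 * 20), 50, 20)
  y <- as.numeric(X %*% rnorm(20, sd = 0.5))  # learnable, so training improves
  frozen <- fit_predictor(model, X, y,
                          config = train_config(epochs = 25, seed = 15,
                                                freeze_encoder = TRUE))
  expect_identical(frozen$net$layers[1:2], enc$layers)
  expect_false(identical(frozen$net$layers[[3]], model$net$layers[[3]]))

  thawed <- fit_predictor(model, X, y,
                          config = train_config(epochs = 25, seed = 15))
  expect_false(identical(thawed$net$layers[1:2], enc$layers))
})

test_that("prediction is a deterministic row-wise forward pass", {
  enc <- make_toy_encoder(16)
  model <- build_predictor(enc, "regression", head_config = list(seed = 17))
  set.seed(18)
  X <- matrix(rnorm(5 * 20), 5, 20)
  p <- predict(model, X)
  dup <- predict(model, X[c(1, 1, 3), ])
  expect_equal(dup[1], dup[2], tolerance = 0)       # same row, same output
  expect_equal(dup[1:2], rep(p[1], 2), tolerance = 1e-12)
  expect_error(predict(model, X[, 1:10]), "columns")
})

test_that("classification heads emit probabilities and reject bad targets", {
  enc <- make_toy_encoder(19)
  model <- build_predictor(enc, "classification", head_config = list(seed = 20))
  set.seed(21)
  X <- matrix(rnorm(60 * 20), 60, 20)
  y <- rbinom(60, 1, 0.3)
  p0 <- predict(model, X)
  expect_true(all(p0 >= 0 & p0 <= 1))
  fitted <- fit_predictor(model, X, y, config = train_config(epochs = 3, seed = 22))
  p <- predict(fitted, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(fit_predictor(model, X, rep(1, 60)), "both classes")
  expect_error(fit_predictor(model, X, y + 0.5), "0/1")
})

test_that("a hand-set network reproduces LeakyReLU forward algebra", {
  # encoder 3 -> 2 -> 1 with alpha = 0.1, head collapsed to pass-through
  enc <- structure(list(
    layers = list(list(W = matrix(c(1, 0, -1, 0, 1, 1), 3, 2), b = c(0.5, -2)),
                  list(W = matrix(c(1, -1), 2, 1), b = 0)),
    spec = autoencoder_spec(3L, 2L, 1L, alpha = 0.1),
    provenance = "target_only", selected_genes = NULL, history = NULL),
    class = "encoder_state")
  model <- build_predictor(enc, "regression", head_config = list(hidden = c(1, 1),
                                                                 seed = 1))
  model$net$layers[[3]] <- list(W = matrix(1, 1, 1), b = 0)
  model$net$layers[[4]] <- list(W = matrix(1, 1, 1), b = 0)
  model$net$layers[[5]] <- list(W = matrix(1, 1, 1), b = 0)

  x <- c(1, 1, 1)
  lrelu <- function(z) ifelse(z > 0, z, 0.1 * z)
  h1 <- lrelu(drop(x %*% matrix(c(1, 0, -1, 0, 1, 1), 3, 2)) + c(0.5, -2))
  h2 <- lrelu(sum(h1 * c(1, -1)))
  expected <- max(h2, 0)  # two ReLU pass-throughs and identity output
  expect_equal(predict(model, matrix(x, 1, 3)), expected, tolerance = 1e-12)
})

test_that("glance summarizes a fitted predictor", {
  enc <- make_toy_encoder(23)
  model <- build_predictor(enc, "regression", head_config = list(seed = 24))
  set.seed(25)
  X <- matrix(rnorm(40 * 20), 40, 20); y <- rnorm(40)
  fitted <- fit_predictor(model, X, y, config = train_config(epochs = 2, seed = 26))
  g <- glance(fitted)
  expect_equal(g$task, "regression")
  expect_true(g$trained)
  expect_gte(g$epochs_run, 1)
})
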