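spec_small <- autoencoder_spec(20L, 8L, 4L)

rand_X <- function(n, m, seed = 1, ids = TRUE) {
  set.seed(seed)
  Z <- matrix(rnorm(n * 3), n, 3)
  X <- Z %*% matrix(rnorm(3 * m), 3, m) + matrix(rnorm(n * m, sd = 0.3), n, m)
  if (ids) dimnames(X) <- list(paste0("S", 1:n), paste0("G", 1:m))
  X
}

test_that("reconstruction loss follows the per-sample squared-norm definition", {
  X <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(reconstruction_loss(X, X), 0)
  expect_equal(reconstruction_loss(matrix(c(1, 0), 1), matrix(c(0, 0), 1)), 1)
  expect_equal(reconstruction_loss(X, matrix(c(0, 3, 2, 6), 2)), 2.5)
  expect_error(reconstruction_loss(X, matrix(0, 1, 2)), "identical shapes")
})

test_that("reconstruction loss is permutation-invariant and duplication-equivariant", {
  set.seed(5)
  X <- matrix(rnorm(40), 8, 5); Xh <- X + matrix(rnorm(40, sd = 0.2), 8, 5)
  base <- reconstruction_loss(X, Xh)
  perm <- sample(8)
  expect_equal(reconstruction_loss(X[perm, ], Xh[perm, ]), base)
  expect_equal(reconstruction_loss(cbind(X, X), cbind(Xh, Xh)), 2 * base)
})

test_that("zero-epoch training is a strict no-op on an explicit init", {
  X <- rand_X(30, 20)
  ae0 <- train_autoencoder(X, spec_small,
                           config = train_config(epochs = 5, seed = 2))
  ae_same <- train_autoencoder(X, spec_small, init = ae0,
                               config = train_config(epochs = 0, seed = 3))
  expect_identical(ae_same$encoder, ae0$encoder)
  expect_identical(ae_same$decoder, ae0$decoder)
})

test_that("training beats the untrained initialization on validation loss", {
  X <- rand_X(400, 60, seed = 42)
  sp <- autoencoder_spec(60L, 16L, 8L)
  ae <- train_autoencoder(X, sp, config = train_config(epochs = 100, seed = 7))
  expect_lt(ae$best_val_loss, ae$history$val_loss[ae$history$epoch == 0])
  expect_gt(nrow(ae$history), 1)
  expect_true(all(is.finite(ae$history$train_loss)))
})

test_that("input width must match the declared spec", {
  expect_error(train_autoencoder(rand_X(30, 10), spec_small,
                                 config = train_config(epochs = 1)),
               "input_dim")
})

test_that("encoder transfer copies source weights exactly before target epochs", {
  Xs <- rand_X(60, 20, seed = 1)
  Xt <- rand_X(30, 20, seed = 2)
  ae_src <- train_autoencoder(Xs, spec_small,
                              config = train_config(epochs = 5, seed = 4))
  src_enc <- extract_encoder(ae_src, "source_only")
  ae_tgt0 <- train_autoencoder(Xt, spec_small, init = src_enc,
                               config = train_config(epochs = 0, seed = 5))
  # weight-transfer fidelity: identical, not merely close
  expect_identical(ae_tgt0$encoder, ae_src$encoder)
})

test_that("two-step pre-training yields the documented shapes and provenance", {
  Xs <- rand_X(60, 20, seed = 3)
  Xt <- rand_X(30, 20, seed = 6)
  enc <- two_step_pretrain(Xs, Xt, spec_small,
                           config = train_config(epochs = 3, seed = 8))
  expect_s3_class(enc, "encoder_state")
  expect_equal(enc$provenance, "two_step")
  expect_equal(dim(enc$layers[[1]]$W), c(20L, 8L))
  expect_equal(dim(enc$layers[[2]]$W), c(8L, 4L))
  expect_setequal(unique(enc$history$phase), c("source", "target"))
  expect_equal(enc$selected_genes, paste0("G", 1:20))

  colnames(Xt) <- rev(colnames(Xt))
  expect_error(two_step_pretrain(Xs, Xt, spec_small), "gene order")
})

test_that("the production architecture yields 5000x512 and 512x200 encoders", {
  sp <- autoencoder_spec()  # defaults
  set.seed(1)
  net <- cellbridge:::.nn_new(cellbridge:::.ae_dims(sp),
                              cellbridge:::.ae_activations(), sp$alpha)
  expect_equal(dim(net$layers[[1]]$W), c(5000L, 512L))
  expect_equal(dim(net$layers[[2]]$W), c(512L, 200L))
})

test_that("encoder variants carry their provenance and share shapes", {
  Xs <- rand_X(60, 20, seed = 9)
  Xt <- rand_X(30, 20, seed = 10)
  cfg <- train_config(epochs = 2, seed = 11)
  encs <- lapply(c("two_step", "target_only", "source_only"), function(v)
    make_encoder_variant(Xs, Xt, spec_small, v, config = cfg))
  expect_equal(vapply(encs, `[[`, character(1), "provenance"),
               c("two_step", "target_only", "source_only"))
  shapes <- lapply(encs, function(e) lapply(e$layers, function(l) dim(l$W)))
  expect_identical(shapes[[1]], shapes[[2]])
  expect_identical(shapes[[1]], shapes[[3]])
  # source_only history holds a single training phase
  expect_false("phase" %in% names(encs[[3]]$history))
})

test_that("identical seeds give identical training histories", {
  X <- rand_X(50, 20, seed = 12)
  cfg <- train_config(epochs = 4, seed = 99)
  ae1 <- train_autoencoder(X, spec_small, config = cfg)
  ae2 <- train_autoencoder(X, spec_small, config = cfg)
  expect_identical(ae1$history, ae2$history)
  expect_identical(ae1$encoder, ae2$encoder)
})

test_that("weights round-trip bit-exactly with provenance and spec checks", {
  Xs <- rand_X(60, 20, seed = 13)
  ae <- train_autoencoder(Xs, spec_small, config = train_config(epochs = 2, seed = 14))
  enc <- extract_encoder(ae, "two_step", selected_genes = paste0("G", 1:20))
  tf <- withr::local_tempfile(fileext = ".rds")
  save_weights(enc, tf)
  back <- load_weights(tf)
  expect_identical(back, enc)
  expect_equal(back$provenance, "two_step")
  expect_identical(back, load_weights(tf, spec = spec_small))
  expect_error(load_weights(tf, spec = autoencoder_spec(20L, 8L, 5L)),
               "mismatch")
  expect_error(save_weights(list(1), withr::local_tempfile()), "unsupported")
})
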