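# closure models exercising the harness without network training; the
# oracle reads the target planted in the first design column
oracle_factory <- function(X, y, fold_seed) function(Xnew) Xnew[, 1]
mean_factory <- function(X, y, fold_seed) {
  mu <- mean(y)
  function(Xnew) rep(mu, nrow(Xnew))
}

test_that("kfold_split gives near-equal, seeded, disjoint folds", {
  ids <- paste0("S", 1:10)
  f <- kfold_split(ids, k = 5, seed = 1)
  expect_equal(as.vector(table(f$fold)), rep(2L, 5))
  expect_identical(f, kfold_split(ids, k = 5, seed = 1))
  expect_false(identical(f$fold, kfold_split(ids, k = 5, seed = 2)$fold))
  expect_error(kfold_split(paste0("S", 1:3), k = 5), "fewer samples")

  f2 <- kfold_split(paste0("S", 1:23), k = 5, seed = 3)
  expect_lte(diff(range(table(f2$fold))), 1)
})

test_that("stratified folds balance a 20% positive binary target", {
  y <- rep(c(1, 0), c(10, 40))
  f <- kfold_split(paste0("S", 1:50), k = 5, seed = 4, stratify_on = y)
  per_fold_pos <- tapply(y, f$fold, sum)
  expect_true(all(per_fold_pos == 2))
})

test_that("run_cv evaluates an oracle and a mean predictor correctly", {
  set.seed(41)
  n <- 500
  y <- rnorm(n)
  task <- list(X = cbind(y, matrix(rnorm(n * 2), n, 2)), y = y,
               sample_ids = paste0("S", 1:n), feature_id = "F1",
               value_kind = "continuous")

  ev_oracle <- run_cv(task, oracle_factory, seed = 1, method_label = "oracle")
  expect_equal(nrow(ev_oracle$per_fold), 5L)
  expect_equal(ev_oracle$aggregate$mean[ev_oracle$aggregate$metric == "mse"], 0)

  ev_mean <- run_cv(task, mean_factory, seed = 1, method_label = "mean")
  mse_mean <- ev_mean$aggregate$mean[ev_mean$aggregate$metric == "mse"]
  expect_gt(mse_mean, 0.8)
  expect_lt(mse_mean, 1.2)
})

test_that("folds are disjoint and exhaustive and rmse == sqrt(mse) per fold", {
  set.seed(42)
  n <- 103
  task <- list(X = matrix(rnorm(n * 2), n, 2), y = rnorm(n),
               sample_ids = paste0("S", 1:n), feature_id = "F1",
               value_kind = "continuous")
  ev <- run_cv(task, mean_factory, seed = 9)
  fa <- ev$fold_assignments
  expect_setequal(fa$sample_id, task$sample_ids)
  expect_equal(sort(unique(fa$fold)), 1:5)
  expect_false(anyDuplicated(fa$sample_id) > 0)
  expect_equal(ev$per_fold$rmse, sqrt(ev$per_fold$mse), tolerance = 1e-12)
  agg <- ev$aggregate[!is.na(ev$aggregate$mean), ]
  expect_true(all(agg$lower <= agg$mean + 1e-12))
  expect_true(all(agg$mean <= agg$upper + 1e-12))
})

test_that("binary tasks report AUC and F1 per fold", {
  set.seed(43)
  n <- 150
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(2 * X[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  task <- list(X = X, y = y, sample_ids = paste0("S", 1:n),
               feature_id = "MUT1", value_kind = "binary")
  factory <- function(X, y, fold_seed) {
    fit_baseline("logistic_lasso", X, y, seed = fold_seed)
  }
  ev <- run_cv(task, factory, seed = 2, method_label = "logistic_lasso")
  expect_setequal(names(ev$per_fold), c("fold", "auc", "f1_binary", "f1_macro"))
  expect_true(all(ev$per_fold$auc > 0.5))
  expect_s3_class(glance(ev), "tbl_df")
  expect_equal(nrow(tidy(ev)), 15L)  # 5 folds x 3 metrics
})

test_that("fold errors are annotated with the fold index", {
  task <- list(X = matrix(rnorm(40), 20, 2), y = rnorm(20),
               sample_ids = paste0("S", 1:20), feature_id = "F1",
               value_kind = "continuous")
  boom <- function(X, y, fold_seed) stop("boom")
  expect_error(run_cv(task, boom, seed = 1), "fold 1: boom")
})

test_that("quartile partition matches interpolated quartiles and the oracle", {
  v <- setNames(as.numeric(1:8), paste0("f", 1:8))
  part <- quartile_partition(v)
  expect_equal(part$q1, 2.75)
  expect_equal(part$q3, 6.25)
  expect_setequal(part$well, c("f1", "f2"))
  expect_setequal(part$poor, c("f7", "f8"))

  same <- setNames(rep(2, 6), paste0("f", 1:6))
  part_same <- quartile_partition(same)
  expect_length(part_same$well, 0)
  expect_length(part_same$poor, 0)

  sym <- setNames(c(-3, -1, 0, 1, 3), paste0("f", 1:5))
  part_sym <- quartile_partition(sym)
  expect_equal(length(part_sym$well), length(part_sym$poor))

  expect_error(quartile_partition(setNames(1:3, c("a", "b", "c"))), "at least 4")

  set.seed(44)
  for (n in c(4, 5, 7, 11, 20, 33, 50)) {
    v <- setNames(rnorm(n), paste0("f", 1:n))
    part <- quartile_partition(v)
    q <- oracle_quartiles(v)
    expect_setequal(part$well, names(v)[v < q["q1"]])
    expect_setequal(part$poor, names(v)[v > q["q3"]])
  }
})

test_that("feature subsampling is identity below the cap and seeded above it", {
  feats <- paste0("m", 1:225)
  expect_identical(subsample_features(feats, cap = 2000), feats)

  many <- paste0("g", 1:5000)
  sub1 <- subsample_features(many, cap = 2000, seed = 5)
  expect_length(sub1, 2000)
  expect_false(anyDuplicated(sub1) > 0)
  expect_identical(sub1, subsample_features(many, cap = 2000, seed = 5))
})
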