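#' Seeded k-fold assignment
#'
#' Random near-equal folds (sizes differ by at most one); the stratified
#' option balances a binary target across folds so every fold sees both
#' classes when possible.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param stratify_on optional 0/1 vector aligned with `sample_ids`.
#' @return A tibble with columns `sample_id` and `fold` (1..k), in the
#'   input sample order.
#' @export
kfold_split <- function(sample_ids, k = 5L, seed = 1L, stratify_on = NULL) {
  n <- length(sample_ids)
  if (n < k) stop("fewer samples (", n, ") than folds (", k, ")", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  if (is.null(stratify_on)) {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  } else {
    stopifnot(length(stratify_on) == n)
    for (cls in unique(stratify_on)) {
      ix <- which(stratify_on == cls)
      fold[ix[sample.int(length(ix))]] <- rep_len(seq_len(k), length(ix))
    }
  }
  tibble::tibble(sample_id = sample_ids, fold = fold)
}

#' Five-fold cross-validation of one feature model
#'
#' The evaluation protocol used for every (feature, method) pair: split
#' the task's samples into `k` folds; for each fold, fit the model on the
#' remaining folds (network models carve their own internal 10%
#' validation set from that training portion) and predict the held-out
#' fold; compute per-fold metrics — MSE, RMSE and Spearman for continuous
#' targets, AUC and F1 (binary and macro) for binary targets — and
#' aggregate them as mean with a t-based 95% CI.
#'
#' @param task an [align_task()] result (fields `X`, `y`, `sample_ids`,
#'   `feature_id`, `value_kind`), or any list with those fields.
#' @param model_factory function `(X, y, fold_seed)` returning either a
#'   fitted object for which `predict(object, X)` yields numeric
#'   predictions, or a plain prediction function `X -> numeric`.
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment and per-fold fits.
#' @param method_label label stored in the result (default
#'   `"model"`).
#' @return An object of class `cv_evaluation`: list with `feature_id`,
#'   `method`, `per_fold` (tibble of fold metrics), `aggregate` (tibble of
#'   mean/lower/upper per metric), `fold_assignments`, `seed`, and
#'   `predictions` (out-of-fold predictions per sample).
#' @export
run_cv <- function(task, model_factory, k = 5L, seed = 1L,
                   method_label = "model") {
  binary <- identical(task$value_kind, "binary")
  folds <- kfold_split(task$sample_ids, k = k, seed = seed,
                       stratify_on = if (binary) task$y)
  stopifnot(all(seq_len(k) %in% folds$fold), !anyDuplicated(folds$sample_id))
  oof <- rep(NA_real_, length(task$y))
  per_fold <- vector("list", k)
  fitted_models <- vector("list", k)
  for (f in seq_len(k)) {
    test_ix <- which(folds$fold == f)
    train_ix <- setdiff(seq_along(task$y), test_ix)
    fit <- tryCatch(
      model_factory(task$X[train_ix, , drop = FALSE], task$y[train_ix],
                    fold_seed = seed * 1000L + f),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e), call. = FALSE))
    X_te <- task$X[test_ix, , drop = FALSE]
    pred <- as.numeric(if (is.function(fit)) fit(X_te) else predict(fit, X_te))
    oof[test_ix] <- pred
    y_te <- task$y[test_ix]
    per_fold[[f]] <- if (binary) {
      tibble::tibble(fold = f,
                     auc = auc(y_te, pred),
                     f1_binary = f1_score(y_te, pred, "binary"),
                     f1_macro = f1_score(y_te, pred, "macro"))
    } else {
      m <- mse(y_te, pred)
      # a degenerate (constant) prediction vector has no rank correlation;
      # recorded as NA rather than aborting the whole evaluation
      rho <- tryCatch(spearman_cor(y_te, pred), error = function(e) NA_real_)
      tibble::tibble(fold = f, mse = m, rmse = sqrt(m), spearman = rho)
    }
    fitted_models[[f]] <- fit
  }
  per_fold <- dplyr::bind_rows(per_fold)
  metric_cols <- setdiff(names(per_fold), "fold")
  aggregate <- dplyr::bind_rows(lapply(metric_cols, function(mc) {
    vals <- per_fold[[mc]][!is.na(per_fold[[mc]])]
    agg <- if (length(vals) >= 2L) aggregate_ci(vals) else {
      tibble::tibble(mean = NA_real_, lower = NA_real_, upper = NA_real_,
                     n = length(vals))
    }
    dplyr::mutate(agg, metric = mc, .before = 1)
  }))
  structure(list(feature_id = task$feature_id, method = method_label,
                 per_fold = per_fold, aggregate = aggregate,
                 fold_assignments = folds, seed = seed,
                 predictions = tibble::tibble(sample_id = task$sample_ids,
                                              fold = folds$fold,
                                              observed = task$y, predicted = oof),
                 models = fitted_models),
            class = "cv_evaluation")
}

#' @export
print.cv_evaluation <- function(x, ...) {
  cat("<cv_evaluation> feature ", x$feature_id, ", method ", x$method, ", ",
      nrow(x$per_fold), " folds\n", sep = "")
  print(x$aggregate)
  invisible(x)
}

#' @export
tidy.cv_evaluation <- function(x, ...) {
  tidyr::pivot_longer(x$per_fold, -"fold", names_to = "metric",
                      values_to = "value") |>
    dplyr::mutate(feature_id = x$feature_id, method = x$method, .before = 1)
}

#' @export
glance.cv_evaluation <- function(x, ...) {
  dplyr::mutate(x$aggregate, feature_id = x$feature_id, method = x$method,
                .before = 1)
}

#' Partition features into well and poorly predicted sets by RMSE quartile
#'
#' Features with cross-validated RMSE strictly below the first quartile
#' are called well predicted; those strictly above the third quartile
#' poorly predicted. Quartiles use the linear-interpolation convention
#' ([stats::quantile()] type 7).
#'
#' @param per_feature_rmse named numeric vector (names = feature ids) or a
#'   two-column data frame `feature_id`, `rmse`.
#' @return List with character vectors `well` and `poor` and the numeric
#'   cutoffs `q1`, `q3`.
#' @export
quartile_partition <- function(per_feature_rmse) {
  if (is.data.frame(per_feature_rmse)) {
    v <- stats::setNames(per_feature_rmse$rmse, per_feature_rmse$feature_id)
  } else v <- per_feature_rmse
  if (length(v) < 4L) stop("need at least 4 features", call. = FALSE)
  if (is.null(names(v))) stop("feature names required", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  list(well = names(v)[v < q[1]], poor = names(v)[v > q[2]],
       q1 = q[1], q3 = q[2])
}

#' Cap the number of features evaluated per measurement type
#'
#' The scale-up protocol evaluates at most `cap` features per measurement
#' type; when the type has more, a seeded uniform sample without
#' replacement of size `cap` is taken, otherwise all features are kept.
#'
#' @param feature_ids character vector.
#' @param cap maximum number to keep (default 2000).
#' @param seed integer seed.
#' @return Character vector of kept feature ids.
#' @export
subsample_features <- function(feature_ids, cap = 2000L, seed = 1L) {
  if (length(feature_ids) <= cap) return(feature_ids)
  set.seed(seed)
  sample(feature_ids, cap)
}
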