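#' Regression and classification evaluation metrics
#'
#' Standard definitions used throughout the benchmarking harness:
#' `mse()` is the mean squared error, `rmse()` its square root,
#' `spearman_cor()` the Spearman rank correlation (average ranks for
#' ties), `auc()` the rank-based probability that a positive outranks a
#' negative (ties counting one half), and `f1_score()` the F1 with binary
#' or macro averaging at a 0.5 decision threshold.
#'
#' @param y observed values (0/1 for the classification metrics).
#' @param y_hat predictions; scores/probabilities for `auc()`.
#' @name metrics
NULL

#' @rdname metrics
#' @export
mse <- function(y, y_hat) {
  .check_pair(y, y_hat)
  mean((y - y_hat)^2)
}

#' @rdname metrics
#' @export
rmse <- function(y, y_hat) sqrt(mse(y, y_hat))

#' @rdname metrics
#' @export
spearman_cor <- function(y, y_hat) {
  .check_pair(y, y_hat)
  if (stats::sd(y) == 0 || stats::sd(y_hat) == 0) {
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(y, y_hat, method = "spearman")
}

#' @rdname metrics
#' @export
auc <- function(y, y_hat) {
  .check_pair(y, y_hat)
  if (!all(y %in% c(0, 1))) stop("auc requires 0/1 labels", call. = FALSE)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("auc requires both classes", call. = FALSE)
  r <- rank(y_hat)  # average ranks => tied pairs count 1/2
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @rdname metrics
#' @param averaging `"binary"` (F1 of the positive class) or `"macro"`
#'   (unweighted mean of per-class F1; the gating metric for mutation
#'   models).
#' @param threshold decision threshold applied to `y_hat` (default 0.5).
#' @export
f1_score <- function(y, y_hat, averaging = c("binary", "macro"),
                     threshold = 0.5) {
  averaging <- match.arg(averaging)
  .check_pair(y, y_hat)
  if (!all(y %in% c(0, 1))) stop("f1 requires 0/1 labels", call. = FALSE)
  pred <- as.numeric(y_hat >= threshold)
  f1_of <- function(cls) {
    tp <- sum(pred == cls & y == cls)
    fp <- sum(pred == cls & y != cls)
    fn <- sum(pred != cls & y == cls)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }
  if (averaging == "binary") f1_of(1) else mean(c(f1_of(0), f1_of(1)))
}

.check_pair <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least two observations", call. = FALSE)
  if (anyNA(y) || anyNA(y_hat)) stop("missing values in metric inputs", call. = FALSE)
  invisible(TRUE)
}

#' Mean with a t-based 95% confidence interval
#'
#' Aggregates per-fold (or per-feature-model) metric values as
#' \eqn{\bar v \pm t_{1-\alpha/2,\,n-1}\, s/\sqrt{n}}. With zero variance
#' the interval collapses to the mean.
#'
#' @param values numeric vector, length at least 2.
#' @param level confidence level (default 0.95).
#' @return A tibble with columns `mean`, `lower`, `upper`, `n`.
#' @export
aggregate_ci <- function(values, level = 0.95) {
  if (length(values) < 2L) stop("need at least two values", call. = FALSE)
  if (anyNA(values)) stop("missing values", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  tibble::tibble(mean = m, lower = m - half, upper = m + half, n = n)
}
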