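#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the two-sample KS statistic
#' \eqn{D = \sup_t |F_x(t) - F_y(t)|} over the two empirical CDFs, with a
#' two-sided p-value from the asymptotic Kolmogorov distribution. This is
#' the per-gene similarity measure used to screen out genes whose
#' expression distribution differs between the source and target domains
#' (negative-transfer control); per-gene sample sizes in that setting are
#' in the hundreds to thousands, where the asymptotic p-value is accurate.
#'
#' @param x,y numeric vectors of finite values, each non-empty.
#' @return Named list with `statistic` (D) and `p_value`.
#' @export
#' @examples
#' ks_two_sample(rnorm(100), rnorm(100))
ks_two_sample <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("samples must be finite", call. = FALSE)
  }
  n_x <- length(x); n_y <- length(y)
  pooled <- c(x, y)
  ord <- order(pooled)
  # +1/n_x steps for x-members, -1/n_y for y-members; sup of |cumsum| over
  # the pooled order is the sup of the ECDF difference. Ties across samples
  # are handled by taking the cumsum at the last of each tied run.
  steps <- c(rep(1 / n_x, n_x), rep(-1 / n_y, n_y))[ord]
  cum <- cumsum(steps)
  sorted <- pooled[ord]
  at_tie_end <- c(diff(sorted) != 0, TRUE)
  d <- max(abs(cum[at_tie_end]))
  n_eff <- n_x * n_y / (n_x + n_y)
  list(statistic = d, p_value = .kolmogorov_sf(sqrt(n_eff) * d))
}

# two-sided asymptotic Kolmogorov survival function
# Q(lambda) = 2 * sum_{k>=1} (-1)^{k-1} exp(-2 k^2 lambda^2)
.kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(101L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment, clipped to 1. A thin validated
#' wrapper over [stats::p.adjust()]; `method = "bonferroni"` is exposed as
#' the conservative alternative.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = method)
}

#' Select genes with similar expression distributions across two domains
#'
#' Runs [ks_two_sample()] for every gene shared by the source and target
#' expression matrices, adjusts the p-values, and selects the `k` genes
#' with the LARGEST adjusted p — i.e. the genes whose distributions are
#' most compatible between domains. Transferring representation learned on
#' the source only helps when the source resembles the target, so genes
#' with strong distribution shift are excluded up front rather than handed
#' to the network.
#'
#' Ties (many genes reach an adjusted p of 1) are broken by smaller D,
#' then lexicographic gene id, making the ranking deterministic.
#'
#' @param source,target [expression_matrix] objects sharing gene ids.
#' @param k number of genes to select.
#' @param method p-value adjustment, see [adjust_pvalues()].
#' @return A tibble of class `feature_selection` with one row per shared
#'   gene: `gene_id`, `ks_statistic`, `p_raw`, `p_adjusted`, `rank`
#'   (1 = most similar) and `selected`; rows ordered by rank. The selected
#'   gene ids, in rank order, are available via [selected_genes()].
#' @export
select_similar_genes <- function(source, target, k, method = "BH") {
  stopifnot(inherits(source, "expression_matrix"), inherits(target, "expression_matrix"))
  shared <- intersect(colnames(source), colnames(target))
  if (!length(shared)) stop("source and target share no genes", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > length(shared)) {
    warning("k = ", k, " exceeds the ", length(shared),
            " shared genes; selecting all of them", call. = FALSE)
    k <- length(shared)
  }
  ks <- lapply(shared, function(g) ks_two_sample(unclass(source)[, g], unclass(target)[, g]))
  d <- vapply(ks, `[[`, numeric(1), "statistic")
  p <- vapply(ks, `[[`, numeric(1), "p_value")
  padj <- adjust_pvalues(p, method = method)
  ord <- order(-padj, d, shared)
  res <- tibble::tibble(
    gene_id = shared[ord],
    ks_statistic = d[ord],
    p_raw = p[ord],
    p_adjusted = padj[ord],
    rank = seq_along(shared),
    selected = seq_along(shared) <= k
  )
  class(res) <- c("feature_selection", class(res))
  attr(res, "k") <- k
  res
}

#' Selected gene ids of a feature-selection result
#' @param x a `feature_selection` tibble from [select_similar_genes()].
#' @return Character vector of selected gene ids in rank order.
#' @export
selected_genes <- function(x) {
  stopifnot(inherits(x, "feature_selection"))
  x$gene_id[x$selected]
}

#' Baseline feature selection / dimension reduction
#'
#' The selectors used by the comparison models: lasso and elastic net keep
#' the columns with nonzero coefficients along a cross-validated
#' regularization path, random forest keeps the top-`k` columns by
#' impurity importance, and PCA returns a fitted orthogonal projection.
#'
#' @param X numeric matrix (n x p), columns are candidate features.
#' @param y numeric response (ignored for `method = "pca"`).
#' @param method one of `"lasso"`, `"en"`, `"rf"`, `"pca"`.
#' @param k number of columns to keep for `"rf"`.
#' @param n_components projection dimension for `"pca"`.
#' @param l1_ratio elastic-net mixing parameter (`alpha` in glmnet).
#' @param seed integer seed controlling CV folds / forest randomness.
#' @return For the supervised methods, an integer vector of selected column
#'   indices; for `"pca"`, a `prcomp`-style projection restricted to
#'   `n_components` components (with `rotation`, `center` and
#'   `explained_variance_ratio`).
#' @export
baseline_feature_select <- function(X, y = NULL,
                                    method = c("lasso", "en", "rf", "pca"),
                                    k = NULL, n_components = NULL,
                                    l1_ratio = 0.5, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least two samples", call. = FALSE)
  if (method != "pca") {
    if (is.null(y)) stop("y is required for supervised selection", call. = FALSE)
    if (stats::sd(y) == 0) stop("y is constant; supervised selection undefined", call. = FALSE)
  }
  switch(method,
    lasso = ,
    en = {
      alpha <- if (method == "lasso") 1 else l1_ratio
      set.seed(seed)
      fit <- glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = 5)
      beta <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1L]
      which(beta != 0)
    },
    rf = {
      if (is.null(k) || k < 1L) stop("rf selection requires k >= 1", call. = FALSE)
      set.seed(seed)
      fit <- randomForest::randomForest(X, y, ntree = 500, importance = FALSE)
      imp <- randomForest::importance(fit)[, 1L]
      utils::head(order(imp, decreasing = TRUE), k)
    },
    pca = {
      if (is.null(n_components)) stop("pca requires n_components", call. = FALSE)
      n_components <- min(n_components, nrow(X) - 1L, ncol(X))
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      list(
        rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
        center = pc$center,
        explained_variance_ratio =
          (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
        n_components = n_components
      )
    })
}

#' Project new data through a fitted PCA selector
#' @param proj result of `baseline_feature_select(method = "pca")`.
#' @param X numeric matrix with the same columns as the training data.
#' @return n x n_components score matrix.
#' @export
pca_project <- function(proj, X) {
  sweep(as.matrix(X), 2L, proj$center) %*% proj$rotation
}
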