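#' Fit one of the comparison models
#'
#' The baseline suite the transfer model is benchmarked against:
#' \describe{
#'   \item{`lasso` / `en`}{penalized linear regression with the
#'     regularization strength chosen by internal cross-validation
#'     ([glmnet::cv.glmnet()]); `en` uses mixing parameter `l1_ratio`
#'     (glmnet's `alpha`, default 0.5), so `l1_ratio = 1` reproduces the
#'     lasso on the same folds and seed.}
#'   \item{`logistic_lasso` / `logistic_en`}{the binomial counterparts for
#'     binary (mutation) targets; predictions are probabilities.}
#'   \item{`rf`}{random forest regression, 500 trees by default.}
#'   \item{`pca_dnn`}{PCA projection to `n_components` (default 200,
#'     matching the bottleneck width so the encoder-vs-PCA comparison is
#'     dimensionally fair) followed by the same 4-layer prediction head
#'     used by the transfer model.}
#'   \item{`dnn_default`}{the full transfer architecture (encoder + head)
#'     trained from default initialization — no pre-training. Identical in
#'     shape to the transfer model; the only difference is the encoder
#'     initialization.}
#' }
#'
#' @param method one of the labels above.
#' @param X numeric matrix (n x p).
#' @param y numeric response (0/1 for the logistic variants).
#' @param config list of method settings: `l1_ratio`, `ntree`,
#'   `n_components`, `spec` (an [autoencoder_spec()] for `dnn_default`),
#'   `head_config`, `train` (a [train_config()] for the network methods),
#'   `nfolds`.
#' @param seed integer seed (internal CV folds, forest, initialization).
#' @return An object of class `baseline_model`.
#' @export
fit_baseline <- function(method = c("lasso", "en", "rf", "logistic_lasso",
                                    "logistic_en", "pca_dnn", "dnn_default"),
                         X, y, config = list(), seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) < 5L) stop("need at least 5 samples", call. = FALSE)
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)", call. = FALSE)
  logistic <- grepl("^logistic_", method)
  if (logistic && !all(y %in% c(0, 1))) {
    stop("logistic models require a binary 0/1 response", call. = FALSE)
  }
  fit <- switch(method,
    lasso = ,
    en = ,
    logistic_lasso = ,
    logistic_en = {
      alpha <- if (method %in% c("lasso", "logistic_lasso")) 1
               else config$l1_ratio %||% 0.5
      family <- if (logistic) "binomial" else "gaussian"
      nfolds <- config$nfolds %||% 5L
      set.seed(seed)
      foldid <- sample(rep_len(seq_len(nfolds), nrow(X)))
      glmnet::cv.glmnet(X, y, alpha = alpha, family = family, foldid = foldid)
    },
    rf = {
      set.seed(seed)
      randomForest::randomForest(X, y, ntree = config$ntree %||% 500L)
    },
    pca_dnn = {
      n_comp <- min(config$n_components %||% 200L, nrow(X) - 1L, ncol(X))
      proj <- baseline_feature_select(X, method = "pca", n_components = n_comp)
      scores <- pca_project(proj, X)
      head_net <- .fit_head_net(scores, y, logistic = FALSE, config, seed)
      list(proj = proj, head = head_net)
    },
    dnn_default = {
      spec <- config$spec %||% autoencoder_spec(
        input_dim = ncol(X),
        hidden_dim = max(2L, min(512L, floor(ncol(X) / 2))),
        bottleneck_dim = max(1L, min(200L, floor(ncol(X) / 4))))
      set.seed(seed)
      ae <- .nn_new(.ae_dims(spec), .ae_activations(), spec$alpha)
      enc <- structure(list(layers = ae$layers[1:2], spec = spec,
                            provenance = "target_only", selected_genes = colnames(X),
                            history = NULL),
                       class = "encoder_state")
      model <- build_predictor(enc, task = "regression",
                               head_config = config$head_config %||% list())
      tc <- config$train %||% train_config()
      tc$seed <- tc$seed %||% seed
      fit_predictor(model, X, y, config = tc)
    })
  structure(list(method = method, fit = fit, seed = seed,
                 n_features = ncol(X), logistic = logistic),
            class = "baseline_model")
}

# train the 4-layer prediction head alone on a low-dimensional input
.fit_head_net <- function(scores, y, logistic, config, seed) {
  hidden <- (config$head_config %||% list())$hidden %||% c(128L, 32L)
  out_act <- if (logistic) "sigmoid" else "identity"
  set.seed(seed)
  net <- .nn_new(c(ncol(scores), hidden, 1L), c("relu", "relu", out_act), 0.1)
  tc <- config$train %||% train_config()
  tc$seed <- NULL  # RNG already seeded above; keep one stream
  loss <- if (logistic) "bce" else "mse"
  fit <- .nn_train(net, as.matrix(scores), matrix(y, ncol = 1L), loss, tc,
                   val_fraction = 0.1)
  list(net = fit$net, history = fit$history)
}

#' Predict from a fitted baseline model
#'
#' Deterministic given the fitted state; logistic variants return
#' probabilities.
#'
#' @param object a `baseline_model`.
#' @param newdata numeric matrix with the training feature count.
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop("newdata has ", ncol(X), " columns; model was fitted on ",
         object$n_features, call. = FALSE)
  }
  switch(object$method,
    lasso = ,
    en = ,
    logistic_lasso = ,
    logistic_en = as.numeric(stats::predict(object$fit, newx = X,
                                            s = "lambda.min",
                                            type = "response")),
    rf = as.numeric(stats::predict(object$fit, X)),
    pca_dnn = as.numeric(.nn_forward(object$fit$head$net,
                                     pca_project(object$fit$proj, X))),
    dnn_default = predict(object$fit, X))
}

#' @export
tidy.baseline_model <- function(x, ...) {
  if (x$method %in% c("lasso", "en", "logistic_lasso", "logistic_en")) {
    cf <- stats::coef(x$fit, s = "lambda.min")
    tibble::tibble(term = rownames(cf), estimate = as.numeric(cf))
  } else {
    stop("tidy() is defined for the penalized-regression baselines", call. = FALSE)
  }
}

#' @export
glance.baseline_model <- function(x, ...) {
  tibble::tibble(method = x$method, n_features = x$n_features, seed = x$seed)
}

#' Layer-shape manifest of a network model
#'
#' Used to assert that the default-initialization network and the
#' transfer model share an identical architecture (the only difference
#' being encoder initialization).
#'
#' @param model a `transfer_predictor` or a `dnn_default`
#'   `baseline_model`.
#' @return Tibble with `layer`, `input_dim`, `output_dim`, `activation`.
#' @export
layer_manifest <- function(model) {
  if (inherits(model, "baseline_model") && model$method == "dnn_default") {
    model <- model$fit
  }
  stopifnot(inherits(model, "transfer_predictor"))
  dplyr::select(tidy(model), "layer", "input_dim", "output_dim", "activation")
}
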