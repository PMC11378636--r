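#' Attach a prediction head to an encoder
#'
#' Builds the full prediction network: the (pre-trained) encoder followed
#' by a 4-layer feedforward head — a merge layer over the bottleneck
#' activations, two fully connected hidden layers (ReLU), and a single
#' output unit (identity for regression, sigmoid for classification). The
#' head uses default (fan-scaled uniform) initialization; the encoder
#' weights are carried over unchanged as the initialization of the joint
#' network.
#'
#' @param encoder an `encoder_state` (see [two_step_pretrain()],
#'   [make_encoder_variant()]).
#' @param task `"regression"` or `"classification"`.
#' @param head_config list with `hidden`, the widths of the two fully
#'   connected layers (default `c(128, 32)`), and optional `seed` for head
#'   initialization.
#' @return An object of class `transfer_predictor` (untrained).
#' @export
build_predictor <- function(encoder, task = c("regression", "classification"),
                            head_config = list()) {
  task <- match.arg(task)
  stopifnot(inherits(encoder, "encoder_state"))
  hidden <- head_config$hidden %||% c(128L, 32L)
  stopifnot(length(hidden) == 2L, all(hidden > 0))
  if (!is.null(head_config$seed)) set.seed(head_config$seed)
  head_dims <- c(encoder$spec$bottleneck_dim, hidden, 1L)
  out_act <- if (task == "regression") "identity" else "sigmoid"
  head <- .nn_new(head_dims, c("relu", "relu", out_act), encoder$spec$alpha)
  structure(list(
    encoder = encoder,
    net = list(layers = c(encoder$layers, head$layers),
               activations = c("lrelu", "lrelu", "relu", "relu", out_act),
               alpha = encoder$spec$alpha),
    n_encoder_layers = length(encoder$layers),
    task = task, hidden = hidden, history = NULL, trained = FALSE
  ), class = "transfer_predictor")
}

#' @export
print.transfer_predictor <- function(x, ...) {
  cat("<transfer_predictor> ", x$task, ", encoder ", x$encoder$provenance,
      " (", x$encoder$spec$input_dim, "->", x$encoder$spec$bottleneck_dim,
      "), head ", paste(x$hidden, collapse = "/"),
      if (x$trained) ", trained" else ", untrained", "\n", sep = "")
  invisible(x)
}

#' Fine-tune a prediction network on a supervised task
#'
#' Trains the joint network (encoder and head together — all layers are
#' updated unless `config$freeze_encoder` is set) with minibatch Adam:
#' mean squared error for regression, binary cross-entropy for
#' classification. A validation fraction is carved from the supplied data
#' (stratified for classification) and the best-validation checkpoint is
#' returned; with a zero-epoch budget the model is returned unchanged.
#'
#' @param model a `transfer_predictor` from [build_predictor()].
#' @param X numeric matrix whose columns match the encoder input.
#' @param y numeric response; must contain both classes for classification.
#' @param val_fraction validation fraction (default 0.1).
#' @param config a [train_config()].
#' @return The trained `transfer_predictor` with a `history` tibble.
#' @export
fit_predictor <- function(model, X, y, val_fraction = 0.1,
                          config = train_config()) {
  stopifnot(inherits(model, "transfer_predictor"))
  X <- as.matrix(X); y <- as.numeric(y)
  if (ncol(X) != model$encoder$spec$input_dim) {
    stop("X has ", ncol(X), " columns; encoder expects ",
         model$encoder$spec$input_dim, call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)", call. = FALSE)
  if (nrow(X) < 10L) stop("need at least 10 samples", call. = FALSE)
  if (model$task == "classification") {
    if (!all(y %in% c(0, 1))) stop("classification requires 0/1 targets", call. = FALSE)
    if (length(unique(y)) < 2L) stop("classification requires both classes", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  loss <- if (model$task == "regression") "mse" else "bce"
  trainable <- rep(TRUE, length(model$net$layers))
  if (config$freeze_encoder) trainable[seq_len(model$n_encoder_layers)] <- FALSE
  strat <- if (model$task == "classification") y
  fit <- .nn_train(model$net, X, matrix(y, ncol = 1L), loss, config,
                   val_fraction = val_fraction, stratify_on = strat,
                   trainable = trainable)
  model$net <- fit$net
  model$history <- fit$history
  model$best_val_loss <- fit$best_val
  model$trained <- TRUE
  # the encoder carried inside reflects the fine-tuned weights
  model$encoder$layers <- fit$net$layers[seq_len(model$n_encoder_layers)]
  model
}

#' Predict from a fitted (or freshly initialized) prediction network
#'
#' Deterministic forward pass. Classification returns probabilities in
#' `[0, 1]`.
#'
#' @param object a `transfer_predictor`.
#' @param newdata numeric matrix whose columns match the encoder input.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.transfer_predictor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$encoder$spec$input_dim) {
    stop("newdata has ", ncol(X), " columns; encoder expects ",
         object$encoder$spec$input_dim, call. = FALSE)
  }
  as.numeric(.nn_forward(object$net, X))
}

#' @export
glance.transfer_predictor <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    provenance = x$encoder$provenance,
    input_dim = x$encoder$spec$input_dim,
    bottleneck_dim = x$encoder$spec$bottleneck_dim,
    trained = x$trained,
    epochs_run = if (is.null(x$history)) NA_integer_ else max(x$history$epoch),
    best_val_loss = x$best_val_loss %||% NA_real_
  )
}

#' @export
tidy.transfer_predictor <- function(x, ...) {
  tibble::tibble(
    layer = seq_along(x$net$layers),
    part = c(rep("encoder", x$n_encoder_layers),
             rep("head", length(x$net$layers) - x$n_encoder_layers)),
    input_dim = vapply(x$net$layers, function(l) nrow(l$W), integer(1)),
    output_dim = vapply(x$net$layers, function(l) ncol(l$W), integer(1)),
    activation = x$net$activations
  )
}
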