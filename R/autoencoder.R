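#' Autoencoder architecture specification
#'
#' Layer widths and activation slope of the symmetric autoencoder used for
#' representation learning: the encoder maps the `input_dim` selected
#' genes through one hidden layer to the bottleneck, `h = s_f(W x + b)`
#' with a LeakyReLU `s_f`, and the decoder mirrors it back,
#' `x_hat = s_g(W' h + b')` with an identity output activation. Defaults
#' (5000/512/200, LeakyReLU slope 0.1) are the production architecture;
#' small data uses proportionally smaller specs.
#'
#' @param input_dim number of input genes.
#' @param hidden_dim width of the single hidden layer.
#' @param bottleneck_dim width of the bottleneck whose activations feed
#'   the prediction head.
#' @param alpha negative slope of the LeakyReLU activations.
#' @return A list of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(input_dim = 5000L, hidden_dim = 512L,
                             bottleneck_dim = 200L, alpha = 0.1) {
  if (!(input_dim > hidden_dim && hidden_dim > bottleneck_dim && bottleneck_dim > 0)) {
    stop("require input_dim > hidden_dim > bottleneck_dim > 0", call. = FALSE)
  }
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 bottleneck_dim = as.integer(bottleneck_dim),
                 alpha = alpha),
            class = "autoencoder_spec")
}

.ae_dims <- function(spec) {
  c(spec$input_dim, spec$hidden_dim, spec$bottleneck_dim,
    spec$hidden_dim, spec$input_dim)
}

.ae_activations <- function() c("lrelu", "lrelu", "lrelu", "identity")

#' Reconstruction loss of an autoencoder
#'
#' The training objective: the per-sample squared Euclidean reconstruction
#' error, averaged over samples,
#' \eqn{\frac{1}{n}\sum_i \lVert x_i - \hat x_i \rVert^2}.
#'
#' @param X,X_hat numeric matrices of identical shape.
#' @return A single number.
#' @export
#' @examples
#' reconstruction_loss(matrix(c(1, 3, 2, 4), 2), matrix(c(0, 3, 2, 6), 2))
reconstruction_loss <- function(X, X_hat) {
  X <- as.matrix(X); X_hat <- as.matrix(X_hat)
  if (!identical(dim(X), dim(X_hat))) {
    stop("X and X_hat must have identical shapes", call. = FALSE)
  }
  sum((X - X_hat)^2) / nrow(X)
}

.new_autoencoder_weights <- function(net, spec, history, val_loss) {
  structure(list(encoder = net$layers[1:2], decoder = net$layers[3:4],
                 spec = spec, history = history, best_val_loss = val_loss),
            class = "autoencoder_weights")
}

.ae_as_net <- function(w) {
  list(layers = c(w$encoder, w$decoder), activations = .ae_activations(),
       alpha = w$spec$alpha)
}

#' Train an autoencoder
#'
#' Gradient training (minibatch Adam) of the symmetric autoencoder against
#' [reconstruction_loss()], holding out a validation fraction; the
#' checkpoint with the best validation loss — which may be the
#' initialization itself — is returned, and the loss trajectory is kept in
#' the `history` field.
#'
#' @param X numeric matrix (n x input_dim), samples in rows.
#' @param spec an [autoencoder_spec()].
#' @param init optional `autoencoder_weights` (or an `encoder_state`, whose
#'   layers seed the encoder side while the decoder is freshly
#'   initialized) used as the starting point instead of random
#'   initialization.
#' @param val_fraction fraction held out for validation (default 0.1, i.e.
#'   train on 90%).
#' @param config a [train_config()].
#' @return An object of class `autoencoder_weights`.
#' @export
train_autoencoder <- function(X, spec, init = NULL, val_fraction = 0.1,
                              config = train_config()) {
  X <- as.matrix(X)
  if (ncol(X) != spec$input_dim) {
    stop("X has ", ncol(X), " columns but spec$input_dim is ", spec$input_dim,
         call. = FALSE)
  }
  if (nrow(X) < 10L) stop("need at least 10 samples for a validation split",
                          call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  net <- .nn_new(.ae_dims(spec), .ae_activations(), spec$alpha)
  if (!is.null(init)) {
    if (inherits(init, "autoencoder_weights")) {
      .check_layer_dims(c(init$encoder, init$decoder), net$layers)
      net$layers <- c(init$encoder, init$decoder)
    } else if (inherits(init, "encoder_state")) {
      .check_layer_dims(init$layers, net$layers[1:2])
      net$layers[1:2] <- init$layers
    } else stop("init must be autoencoder_weights or encoder_state", call. = FALSE)
  }
  fit <- .nn_train(net, X, X, "sse_per_sample", config, val_fraction = val_fraction)
  .new_autoencoder_weights(fit$net, spec, fit$history, fit$best_val)
}

.check_layer_dims <- function(given, expected) {
  for (l in seq_along(expected)) {
    if (!identical(dim(given[[l]]$W), dim(expected[[l]]$W))) {
      stop("layer ", l, " weight shape ", paste(dim(given[[l]]$W), collapse = "x"),
           " does not match expected ", paste(dim(expected[[l]]$W), collapse = "x"),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Extract the encoder from trained autoencoder weights
#'
#' @param weights an `autoencoder_weights` object.
#' @param provenance how the encoder was obtained: `"two_step"`
#'   (source-pretrained then target-refined), `"target_only"` or
#'   `"source_only"`. Recorded at creation and immutable.
#' @param selected_genes optional ordered gene ids the encoder expects as
#'   input columns.
#' @return An object of class `encoder_state`.
#' @export
extract_encoder <- function(weights,
                            provenance = c("two_step", "target_only", "source_only"),
                            selected_genes = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(weights, "autoencoder_weights"))
  if (!is.null(selected_genes) &&
      length(selected_genes) != weights$spec$input_dim) {
    stop("selected_genes length must equal spec$input_dim", call. = FALSE)
  }
  structure(list(layers = weights$encoder, spec = weights$spec,
                 provenance = provenance, selected_genes = selected_genes,
                 history = weights$history),
            class = "encoder_state")
}

#' @export
print.encoder_state <- function(x, ...) {
  cat("<encoder_state> ", x$spec$input_dim, " -> ", x$spec$hidden_dim, " -> ",
      x$spec$bottleneck_dim, " (provenance: ", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Encode samples to the bottleneck representation
#' @param encoder an `encoder_state`.
#' @param X numeric matrix with `spec$input_dim` columns.
#' @return n x bottleneck_dim matrix of activations.
#' @export
encode <- function(encoder, X) {
  stopifnot(inherits(encoder, "encoder_state"))
  X <- as.matrix(X)
  if (ncol(X) != encoder$spec$input_dim) {
    stop("X has ", ncol(X), " columns; encoder expects ", encoder$spec$input_dim,
         call. = FALSE)
  }
  net <- list(layers = encoder$layers, activations = c("lrelu", "lrelu"),
              alpha = encoder$spec$alpha)
  .nn_forward(net, X)
}

.check_gene_order <- function(source_X, target_X) {
  cs <- colnames(source_X); ct <- colnames(target_X)
  if (ncol(source_X) != ncol(target_X)) {
    stop("source and target must share the same selected genes in the same order",
         call. = FALSE)
  }
  if (!is.null(cs) && !is.null(ct) && !identical(cs, ct)) {
    stop("gene order mismatch between source and target matrices", call. = FALSE)
  }
  invisible(cs)
}

#' Two-step pre-training with encoder weight transfer
#'
#' The parameter-transfer procedure at the heart of the package:
#' \enumerate{
#'   \item train an autoencoder on the large source domain from default
#'     initialization;
#'   \item copy its encoder weights into a fresh autoencoder as the
#'     initialization for the target domain (the decoder is re-initialized
#'     by the default scheme);
#'   \item train that autoencoder on the small target domain;
#'   \item extract the refined encoder.
#' }
#' Both matrices must carry the same selected genes in the same column
#' order. The returned encoder has provenance `"two_step"` and a history
#' holding both training phases.
#'
#' @param source_X,target_X numeric matrices (samples x selected genes).
#' @param spec an [autoencoder_spec()].
#' @param config a [train_config()]; applied to both phases.
#' @param val_fraction validation fraction for both phases.
#' @return An `encoder_state` with provenance `"two_step"`.
#' @export
two_step_pretrain <- function(source_X, target_X, spec,
                              config = train_config(), val_fraction = 0.1) {
  genes <- .check_gene_order(source_X, target_X)
  ae_src <- train_autoencoder(source_X, spec, val_fraction = val_fraction,
                              config = config)
  src_enc <- extract_encoder(ae_src, "source_only", selected_genes = genes)
  ae_tgt <- train_autoencoder(target_X, spec, init = src_enc,
                              val_fraction = val_fraction, config = config)
  enc <- extract_encoder(ae_tgt, "two_step", selected_genes = genes)
  enc$history <- dplyr::bind_rows(
    dplyr::mutate(ae_src$history, phase = "source"),
    dplyr::mutate(ae_tgt$history, phase = "target"))
  enc$best_val_loss <- ae_tgt$best_val_loss
  enc
}

#' Build an encoder under one of the three provenance variants
#'
#' `"two_step"` is the full transfer procedure ([two_step_pretrain()]);
#' `"target_only"` trains an autoencoder on the target domain from default
#' initialization (no transfer); `"source_only"` trains on the source
#' domain only. The three variants share identical layer shapes, so
#' downstream comparisons isolate the effect of the initialization.
#'
#' @inheritParams two_step_pretrain
#' @param variant one of `"two_step"`, `"target_only"`, `"source_only"`.
#' @return An `encoder_state` with matching provenance.
#' @export
make_encoder_variant <- function(source_X, target_X, spec,
                                 variant = c("two_step", "target_only", "source_only"),
                                 config = train_config(), val_fraction = 0.1) {
  variant <- match.arg(variant)
  if (variant == "two_step") {
    return(two_step_pretrain(source_X, target_X, spec, config, val_fraction))
  }
  X <- if (variant == "target_only") target_X else source_X
  genes <- colnames(X)
  ae <- train_autoencoder(as.matrix(X), spec, val_fraction = val_fraction,
                          config = config)
  enc <- extract_encoder(ae, variant, selected_genes = genes)
  enc$best_val_loss <- ae$best_val_loss
  enc
}

#' Reconstruction loss of an encoder's autoencoder on held-out data
#'
#' Rebuilds the full autoencoder net from stored weights and evaluates
#' [reconstruction_loss()] on `X`. For encoders (which carry no decoder)
#' this is only defined when created through [train_autoencoder()]
#' variants in this package; use [train_autoencoder()] results directly.
#'
#' @param weights an `autoencoder_weights` object.
#' @param X evaluation matrix.
#' @return A single number.
#' @export
evaluate_reconstruction <- function(weights, X) {
  stopifnot(inherits(weights, "autoencoder_weights"))
  net <- .ae_as_net(weights)
  reconstruction_loss(X, .nn_forward(net, as.matrix(X)))
}
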