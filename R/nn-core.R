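# Small feedforward-network engine used by the autoencoder and the
# prediction head. Dense layers only, trained by minibatch Adam on a
# squared-error or binary cross-entropy objective, with early stopping on
# a held-out validation split and best-validation checkpointing. Sizes in
# this package (thousands of samples, hundreds to thousands of features,
# two or three hidden layers) run comfortably on BLAS matrix products.

#' Training configuration for the network-based models
#'
#' @param epochs maximum number of passes over the training split. An
#'   epoch budget of 0 is a valid no-op: the initial weights are returned
#'   unchanged.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param patience early-stopping patience, in epochs without validation
#'   improvement; `Inf` disables early stopping.
#' @param seed integer seed for the validation split, shuffling and weight
#'   initialization; `NULL` leaves the RNG state alone.
#' @param freeze_encoder if `TRUE`, [fit_predictor()] updates only the
#'   prediction head and leaves encoder weights untouched.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 32L, learning_rate = 1e-3,
                         patience = 20L, seed = NULL, freeze_encoder = FALSE) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0, patience >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = patience,
                 seed = seed, freeze_encoder = isTRUE(freeze_encoder)),
            class = "train_config")
}

# Glorot (fan-scaled) uniform initialization, the conventional default for
# dense layers
.nn_init_layer <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  list(W = matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out),
       b = numeric(fan_out))
}

.nn_new <- function(dims, activations, alpha = 0.1) {
  stopifnot(length(dims) >= 2L, length(activations) == length(dims) - 1L)
  layers <- lapply(seq_len(length(dims) - 1L), function(l)
    .nn_init_layer(dims[l], dims[l + 1L]))
  list(layers = layers, activations = activations, alpha = alpha)
}

.nn_act <- function(Z, act, alpha) {
  switch(act,
    lrelu = ifelse(Z > 0, Z, alpha * Z),
    relu = pmax(Z, 0),
    identity = Z,
    sigmoid = 1 / (1 + exp(-Z)),
    stop("unknown activation: ", act))
}

.nn_act_grad <- function(Z, act, alpha) {
  switch(act,
    lrelu = ifelse(Z > 0, 1, alpha),
    relu = (Z > 0) * 1,
    identity = array(1, dim = dim(Z)),
    stop("gradient through ", act, " handled at the loss"))
}

# forward pass; keep = TRUE retains pre- and post-activations for backprop
.nn_forward <- function(net, X, keep = FALSE) {
  A <- X
  As <- if (keep) vector("list", length(net$layers) + 1L)
  Zs <- if (keep) vector("list", length(net$layers))
  if (keep) As[[1L]] <- X
  for (l in seq_along(net$layers)) {
    Z <- A %*% net$layers[[l]]$W
    Z <- sweep(Z, 2L, net$layers[[l]]$b, "+")
    A <- .nn_act(Z, net$activations[l], net$alpha)
    if (keep) { Zs[[l]] <- Z; As[[l + 1L]] <- A }
  }
  if (keep) list(out = A, As = As, Zs = Zs) else A
}

# loss value and gradient wrt the last pre-activation.
# "sse_per_sample": (1/n) sum_i ||x_i - xhat_i||^2 (identity output)
# "mse": mean squared error on a single output (identity output)
# "bce": binary cross-entropy (sigmoid output; gradient simplifies)
.nn_loss <- function(kind, A_last, target) {
  n <- nrow(A_last)
  switch(kind,
    sse_per_sample = {
      R <- A_last - target
      list(value = sum(R^2) / n, dZ = 2 * R / n)
    },
    mse = {
      R <- A_last - target
      list(value = mean(R^2), dZ = 2 * R / (n * ncol(A_last)))
    },
    bce = {
      eps <- 1e-12
      p <- pmin(pmax(A_last, eps), 1 - eps)
      list(value = -mean(target * log(p) + (1 - target) * log(1 - p)),
           dZ = (A_last - target) / n)
    },
    stop("unknown loss: ", kind))
}

.nn_loss_value <- function(kind, net, X, target) {
  .nn_loss(kind, .nn_forward(net, X), target)$value
}

# one Adam update over a minibatch; returns net and optimizer state.
# The output layer's activation (identity or sigmoid) is folded into the
# loss gradient, so the backward loop only differentiates hidden layers.
.nn_step <- function(net, opt, X, target, loss_kind, lr, trainable) {
  fw <- .nn_forward(net, X, keep = TRUE)
  ls <- .nn_loss(loss_kind, fw$out, target)
  L <- length(net$layers)
  dZ <- ls$dZ
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (l in rev(seq_len(L))) {
    if (l < L) dZ <- dZ * .nn_act_grad(fw$Zs[[l]], net$activations[l], net$alpha)
    if (trainable[l]) {
      gW <- crossprod(fw$As[[l]], dZ)
      gb <- colSums(dZ)
      opt$steps[l] <- opt$steps[l] + 1L
      opt$mW[[l]] <- b1 * opt$mW[[l]] + (1 - b1) * gW
      opt$vW[[l]] <- b2 * opt$vW[[l]] + (1 - b2) * gW^2
      opt$mb[[l]] <- b1 * opt$mb[[l]] + (1 - b1) * gb
      opt$vb[[l]] <- b2 * opt$vb[[l]] + (1 - b2) * gb^2
      corr1 <- 1 - b1^opt$steps[l]; corr2 <- 1 - b2^opt$steps[l]
      net$layers[[l]]$W <- net$layers[[l]]$W -
        lr * (opt$mW[[l]] / corr1) / (sqrt(opt$vW[[l]] / corr2) + eps)
      net$layers[[l]]$b <- net$layers[[l]]$b -
        lr * (opt$mb[[l]] / corr1) / (sqrt(opt$vb[[l]] / corr2) + eps)
    }
    if (l > 1L) dZ <- dZ %*% t(net$layers[[l]]$W)
  }
  list(net = net, opt = opt, loss = ls$value)
}

.nn_opt_init <- function(net) {
  zW <- lapply(net$layers, function(ly) array(0, dim = dim(ly$W)))
  zb <- lapply(net$layers, function(ly) numeric(length(ly$b)))
  list(mW = zW, vW = zW, mb = zb, vb = zb,
       steps = integer(length(net$layers)))
}

# held-out split; stratified keeps the class balance of a binary target
.nn_val_split <- function(n, val_fraction, y = NULL, stratify = FALSE) {
  n_val <- max(1L, round(n * val_fraction))
  if (n_val >= n) stop("validation split leaves no training samples", call. = FALSE)
  if (stratify && !is.null(y)) {
    idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
      take <- max(1L, round(length(ix) * val_fraction))
      sample(ix, min(take, length(ix) - 1L))
    }))
    sort(idx)
  } else {
    sort(sample.int(n, n_val))
  }
}

# full training loop. Returns the best-validation checkpoint (the
# initialization itself counts as epoch 0, so a training run can never
# return weights worse on validation than its starting point) plus a
# history tibble of train/validation loss per epoch.
.nn_train <- function(net, X, target, loss_kind, config,
                      val_fraction = 0.1, stratify_on = NULL,
                      trainable = rep(TRUE, length(net$layers))) {
  n <- nrow(X)
  val_idx <- .nn_val_split(n, val_fraction, y = stratify_on,
                           stratify = !is.null(stratify_on))
  tr_idx <- setdiff(seq_len(n), val_idx)
  X_tr <- X[tr_idx, , drop = FALSE]; T_tr <- target[tr_idx, , drop = FALSE]
  X_va <- X[val_idx, , drop = FALSE]; T_va <- target[val_idx, , drop = FALSE]

  opt <- .nn_opt_init(net)
  best <- list(net = net, val = .nn_loss_value(loss_kind, net, X_va, T_va))
  hist <- list(tibble::tibble(
    epoch = 0L, train_loss = .nn_loss_value(loss_kind, net, X_tr, T_tr),
    val_loss = best$val))
  wait <- 0L
  lr <- config$learning_rate
  if (config$epochs > 0L) for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(nrow(X_tr))
    starts <- seq(1L, nrow(X_tr), by = config$batch_size)
    for (s in starts) {
      ix <- perm[s:min(s + config$batch_size - 1L, nrow(X_tr))]
      st <- .nn_step(net, opt, X_tr[ix, , drop = FALSE], T_tr[ix, , drop = FALSE],
                     loss_kind, lr, trainable)
      net <- st$net; opt <- st$opt
      if (!is.finite(st$loss)) {
        stop("non-finite training loss at epoch ", epoch, call. = FALSE)
      }
    }
    tr_loss <- .nn_loss_value(loss_kind, net, X_tr, T_tr)
    va_loss <- .nn_loss_value(loss_kind, net, X_va, T_va)
    if (!is.finite(tr_loss) || !is.finite(va_loss)) {
      stop("non-finite loss at epoch ", epoch, call. = FALSE)
    }
    hist[[length(hist) + 1L]] <- tibble::tibble(
      epoch = epoch, train_loss = tr_loss, val_loss = va_loss)
    if (va_loss < best$val) {
      best <- list(net = net, val = va_loss); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(net = best$net, best_val = best$val,
       history = dplyr::bind_rows(hist), val_idx = val_idx)
}
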