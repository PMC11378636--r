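#' Persist and restore model weights
#'
#' Weight containers (`encoder_state`, `autoencoder_weights`,
#' `transfer_predictor`, `baseline_model`) are written with R's native
#' serialization (RDS), which round-trips numeric weights bit-exactly and
#' preserves layer dimensions and the encoder provenance tag.
#'
#' @param state an `encoder_state`, `autoencoder_weights`,
#'   `transfer_predictor` or `baseline_model`.
#' @param path file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_weights <- function(state, path) {
  if (!inherits(state, c("encoder_state", "autoencoder_weights",
                         "transfer_predictor", "baseline_model"))) {
    stop("unsupported state type: ", paste(class(state), collapse = "/"),
         call. = FALSE)
  }
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_weights
#' @param spec optional [autoencoder_spec()]; when given, the loaded
#'   object's layer dimensions are validated against it and a mismatch is
#'   an error.
#' @return `load_weights()` returns the restored object, identical to the
#'   one saved.
#' @export
load_weights <- function(path, spec = NULL) {
  if (!file.exists(path)) stop("weight file not found: ", path, call. = FALSE)
  state <- readRDS(path)
  if (!inherits(state, c("encoder_state", "autoencoder_weights",
                         "transfer_predictor", "baseline_model"))) {
    stop("file does not contain a recognized weight container", call. = FALSE)
  }
  if (!is.null(spec)) {
    found <- if (inherits(state, "transfer_predictor")) state$encoder$spec
             else state$spec
    if (is.null(found)) stop("loaded object carries no architecture spec", call. = FALSE)
    same <- identical(found$input_dim, spec$input_dim) &&
      identical(found$hidden_dim, spec$hidden_dim) &&
      identical(found$bottleneck_dim, spec$bottleneck_dim)
    if (!same) {
      stop(sprintf("architecture mismatch: file has %d/%d/%d, expected %d/%d/%d",
                   found$input_dim, found$hidden_dim, found$bottleneck_dim,
                   spec$input_dim, spec$hidden_dim, spec$bottleneck_dim),
           call. = FALSE)
    }
  }
  state
}
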