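#' Plot a feature-selection result
#'
#' KS statistic against adjusted p per gene, with the selected
#' (distribution-compatible) genes highlighted.
#'
#' @param object a `feature_selection` tibble from
#'   [select_similar_genes()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.feature_selection <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$ks_statistic, y = .data$p_adjusted,
                               colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166AC",
                                            `FALSE` = "#B2182B")) +
    ggplot2::labs(x = "KS statistic D", y = "BH-adjusted p",
                  colour = "selected",
                  title = "Domain-similarity gene selection") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' One point per fold and metric, with the aggregate mean and 95% CI
#' overlaid.
#'
#' @param object a `cv_evaluation` from [run_cv()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cv_evaluation <- function(object, ...) {
  long <- tidy(object)
  agg <- object$aggregate
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::geom_pointrange(data = agg,
                             ggplot2::aes(x = .data$metric, y = .data$mean,
                                          ymin = .data$lower, ymax = .data$upper),
                             colour = "#2166AC") +
    ggplot2::labs(title = paste0("Cross-validation: ", object$feature_id,
                                 " (", object$method, ")"),
                  x = NULL, y = "fold value") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Train and validation loss per epoch for any model carrying a
#' `history` tibble (autoencoders, prediction networks).
#'
#' @param model an `autoencoder_weights`, `encoder_state` or
#'   `transfer_predictor`.
#' @return A ggplot object.
#' @export
plot_training_history <- function(model) {
  hist <- model$history
  if (is.null(hist)) stop("model carries no training history", call. = FALSE)
  long <- tidyr::pivot_longer(hist, dplyr::any_of(c("train_loss", "val_loss")),
                              names_to = "split", values_to = "loss")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                          colour = .data$split))
  if ("phase" %in% names(hist)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$phase), scales = "free")
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(title = "Training history", y = "loss") +
    ggplot2::theme_minimal()
}

#' Plot a transfer-benefit study
#'
#' Paired per-seed comparison of the three encoder variants on target
#' validation reconstruction loss and downstream test Spearman.
#'
#' @param study tibble from [transfer_benefit_study()].
#' @return A ggplot object.
#' @export
plot_transfer_benefit <- function(study) {
  long <- tidyr::pivot_longer(study, c("target_val_recon", "test_spearman"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variant, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$seed), alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$variant), size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(title = "Encoder provenance comparison", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
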