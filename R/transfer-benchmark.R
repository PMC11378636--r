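#' Compare the three encoder provenances on one dataset pair
#'
#' Trains the two-step, target-only and source-only autoencoders at equal
#' epoch budgets (the same [train_config()] for every phase) and
#' evaluates each variant's reconstruction loss on a common held-out
#' target validation split — the split every target-domain training run
#' itself used, which the source-only variant never saw.
#'
#' @param source_X,target_X numeric matrices (samples x selected genes),
#'   same genes and order.
#' @param spec an [autoencoder_spec()].
#' @param config a [train_config()]; its `seed` fixes the shared target
#'   validation split.
#' @param val_fraction validation fraction (default 0.1).
#' @return List with `encoders` (named list of `encoder_state`),
#'   `weights` (named list of `autoencoder_weights`) and `metrics`, a
#'   tibble with `variant` and `target_val_recon`.
#' @export
compare_encoder_variants <- function(source_X, target_X, spec,
                                     config = train_config(),
                                     val_fraction = 0.1) {
  genes <- .check_gene_order(source_X, target_X)
  source_X <- as.matrix(source_X); target_X <- as.matrix(target_X)
  ae_src <- train_autoencoder(source_X, spec, val_fraction = val_fraction,
                              config = config)
  ae_two <- train_autoencoder(target_X, spec,
                              init = extract_encoder(ae_src, "source_only"),
                              val_fraction = val_fraction, config = config)
  ae_tgt <- train_autoencoder(target_X, spec, val_fraction = val_fraction,
                              config = config)
  # reproduce the (seeded) validation split the target trainings used
  if (!is.null(config$seed)) set.seed(config$seed)
  val_idx <- .nn_val_split(nrow(target_X), val_fraction)
  X_va <- target_X[val_idx, , drop = FALSE]
  weights <- list(two_step = ae_two, target_only = ae_tgt, source_only = ae_src)
  encoders <- list(
    two_step = extract_encoder(ae_two, "two_step", selected_genes = genes),
    target_only = extract_encoder(ae_tgt, "target_only", selected_genes = genes),
    source_only = extract_encoder(ae_src, "source_only", selected_genes = genes))
  metrics <- tibble::tibble(
    variant = names(weights),
    target_val_recon = vapply(weights, function(w)
      evaluate_reconstruction(w, X_va), numeric(1)))
  list(encoders = encoders, weights = weights, metrics = metrics,
       val_idx = val_idx)
}

#' Transfer-benefit study on the synthetic two-domain scenario
#'
#' The package's end-to-end evidence that source pre-training helps when
#' the target domain is small: over several generator seeds, (i) generate
#' the paired domains, (ii) select the distribution-compatible genes,
#' (iii) build all three encoder variants at equal budgets, and (iv)
#' fine-tune a prediction network per variant on held-out continuous
#' features, recording the target validation reconstruction loss and the
#' held-out-test Spearman correlation.
#'
#' @param config a [synthetic_config()]; the `seed` field is overridden
#'   per repetition by `seeds`.
#' @param seeds integer vector of generator seeds (one repetition each).
#' @param spec optional [autoencoder_spec()]; defaults to
#'   selected-genes/64/16 with LeakyReLU slope 0.1.
#' @param pretrain_config [train_config()] for autoencoder phases.
#' @param fit_config [train_config()] for supervised fine-tuning.
#' @param head_config prediction-head settings (default hidden 32/16,
#'   sized for the small bottleneck).
#' @param n_features number of continuous features fine-tuned per seed.
#' @param test_fraction held-out test fraction for the downstream task.
#' @return A tibble with one row per (seed, variant): `seed`, `variant`,
#'   `target_val_recon`, `test_spearman` (mean over the features).
#' @export
transfer_benefit_study <- function(config = synthetic_config(),
                                   seeds = 1:5,
                                   spec = NULL,
                                   pretrain_config = train_config(epochs = 60, patience = 15),
                                   fit_config = train_config(epochs = 30, patience = 10),
                                   head_config = list(hidden = c(32L, 16L)),
                                   n_features = 3L,
                                   test_fraction = 0.25) {
  rows <- list()
  for (s in seeds) {
    cfg <- config; cfg$seed <- s
    dom <- generate_domains(cfg)
    sel <- select_similar_genes(dom$source, dom$target,
                                k = cfg$n_genes - cfg$n_shifted_genes)
    genes <- selected_genes(sel)
    sp <- spec %||% autoencoder_spec(length(genes), 64L, 16L)
    src_X <- unclass(dom$source)[, genes, drop = FALSE]
    tgt_X <- unclass(dom$target)[, genes, drop = FALSE]
    pc <- pretrain_config; pc$seed <- s * 100L
    cmp <- compare_encoder_variants(src_X, tgt_X, sp, config = pc)

    feats <- colnames(dom$measurements)[seq_len(min(n_features,
                                                    ncol(dom$measurements)))]
    set.seed(s * 100L + 7L)
    n <- nrow(tgt_X)
    test_idx <- sort(sample.int(n, max(1L, round(n * test_fraction))))
    train_idx <- setdiff(seq_len(n), test_idx)
    for (variant in names(cmp$encoders)) {
      sp_feat <- vapply(feats, function(f) {
        task <- align_task(dom$target, dom$measurements, f, genes)
        fc <- fit_config; fc$seed <- s * 100L + 11L
        model <- build_predictor(cmp$encoders[[variant]], "regression",
                                 head_config = head_config)
        model <- fit_predictor(model, task$X[train_idx, , drop = FALSE],
                               task$y[train_idx], config = fc)
        spearman_cor(task$y[test_idx],
                     predict(model, task$X[test_idx, , drop = FALSE]))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = s, variant = variant,
        target_val_recon =
          cmp$metrics$target_val_recon[cmp$metrics$variant == variant],
        test_spearman = mean(sp_feat))
    }
  }
  dplyr::bind_rows(rows)
}
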