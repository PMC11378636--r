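#' Configuration of the synthetic two-domain generator
#'
#' The generator emulates the statistical structure the transfer method
#' assumes: a large source domain and a small target domain share a
#' latent factor model, a configurable subset of genes is
#' distribution-shifted in the target (the genes a domain-similarity
#' filter should reject), continuous measurements are driven by the
#' latent factors with one mild nonlinearity, and binary measurements are
#' imbalanced. Defaults are the desk-scale study scenario: 8 latent
#' factors, 300 genes of which 30 are shifted by 5 gene-level SDs, 2000
#' source and 250 target samples, 20 continuous and 5 binary measurement
#' features.
#'
#' @param latent_dim number of shared latent factors.
#' @param n_source,n_target samples per domain.
#' @param n_genes genes per domain (shared identifiers).
#' @param n_shifted_genes number of target genes receiving a location
#'   shift.
#' @param shift_magnitude shift size in units of the gene's marginal SD.
#' @param domain_shift_sd SD (in units of each gene's marginal SD) of the
#'   mild per-gene mean offsets applied to every target gene, emulating
#'   the systematic but modest domain difference between tumors and cell
#'   lines that makes a second, target-domain pre-training step
#'   worthwhile. 0 makes the non-shifted genes identically distributed
#'   across domains.
#' @param loading_scale SD of the factor loadings.
#' @param noise_sd SD of the per-gene observation noise.
#' @param target_noise_sd SD of the noise on continuous measurements.
#' @param n_continuous_features,n_binary_features measurement counts.
#' @param positive_rate expected positive fraction of binary features,
#'   in (0, 1).
#' @param missing_rate fraction of continuous measurement entries set to
#'   missing (default 0: complete tables).
#' @param seed integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(latent_dim = 8L, n_source = 2000L, n_target = 250L,
                             n_genes = 300L, n_shifted_genes = 30L,
                             shift_magnitude = 5, domain_shift_sd = 0.2,
                             loading_scale = 1,
                             noise_sd = 0.5, target_noise_sd = 0.5,
                             n_continuous_features = 20L,
                             n_binary_features = 5L, positive_rate = 0.2,
                             missing_rate = 0, seed = 1L) {
  stopifnot(latent_dim >= 1, n_source >= 2, n_target >= 2, n_genes >= 1,
            n_shifted_genes >= 0, n_shifted_genes <= n_genes,
            shift_magnitude >= 0, domain_shift_sd >= 0,
            loading_scale > 0, noise_sd >= 0,
            target_noise_sd >= 0, n_continuous_features >= 0,
            n_binary_features >= 0,
            positive_rate > 0, positive_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a paired two-domain dataset with known ground truth
#'
#' Draws standard-normal latent factors `Z` per sample, forms gene values
#' `Z %*% t(loadings) + noise` with loadings shared across domains, then
#' adds `shift_magnitude` marginal SDs to a designated gene subset of the
#' target domain only. Continuous measurement features are
#' `g(Z) %*% beta + noise`, where `g` appends the centered square of the
#' first factor (so a nonlinear model can beat a linear one); binary
#' features threshold a latent logistic score at the quantile matching
#' `positive_rate`. Measurements exist for target-domain samples.
#'
#' @param config a [synthetic_config()].
#' @return List with `source` and `target` ([expression_matrix]),
#'   `measurements` (a [measurement_table] of the continuous features),
#'   `mutations` (a binary [measurement_table]; `NULL` when
#'   `n_binary_features` is 0), and `truth` — a record of the loadings,
#'   coefficients, shifted gene ids, latent factors, the noiseless
#'   continuous signal and the per-feature noise ceiling (Spearman
#'   correlation between a feature and its noiseless component — the
#'   rank correlation a perfect model of the signal would attain).
#' @export
generate_domains <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  d <- config$latent_dim; m <- config$n_genes
  genes <- sprintf("G%04d", seq_len(m))
  src_ids <- sprintf("SRC%05d", seq_len(config$n_source))
  tgt_ids <- sprintf("TGT%05d", seq_len(config$n_target))

  loadings <- matrix(stats::rnorm(m * d, sd = config$loading_scale), m, d,
                     dimnames = list(genes, NULL))
  Z_src <- matrix(stats::rnorm(config$n_source * d), config$n_source, d)
  Z_tgt <- matrix(stats::rnorm(config$n_target * d), config$n_target, d)

  make_expr <- function(Z, ids) {
    E <- Z %*% t(loadings) +
      matrix(stats::rnorm(length(ids) * m, sd = config$noise_sd), length(ids), m)
    dimnames(E) <- list(ids, genes)
    E
  }
  src <- make_expr(Z_src, src_ids)
  tgt <- make_expr(Z_tgt, tgt_ids)
  gene_sd <- sqrt(rowSums(loadings^2) + config$noise_sd^2)

  # mild systematic domain offsets on every target gene
  domain_offsets <- stats::rnorm(m, sd = config$domain_shift_sd) * gene_sd
  if (config$domain_shift_sd > 0) tgt <- sweep(tgt, 2L, domain_offsets, "+")

  shifted <- character(0)
  if (config$n_shifted_genes > 0) {
    shifted <- sample(genes, config$n_shifted_genes)
    tgt[, shifted] <- sweep(tgt[, shifted, drop = FALSE], 2L,
                            config$shift_magnitude * gene_sd[shifted], "+")
  }

  # continuous features: linear in the factors plus a centered square of
  # the first factor
  G_tgt <- cbind(Z_tgt, Z_tgt[, 1]^2 - 1)
  n_cont <- config$n_continuous_features
  meas <- NULL; beta <- NULL; signal <- NULL; ceiling <- NULL
  if (n_cont > 0) {
    beta <- matrix(stats::rnorm((d + 1L) * n_cont), d + 1L, n_cont)
    signal <- G_tgt %*% beta
    noise <- matrix(stats::rnorm(config$n_target * n_cont,
                                 sd = config$target_noise_sd),
                    config$n_target, n_cont)
    vals <- signal + noise
    feat <- sprintf("M%03d", seq_len(n_cont))
    dimnames(vals) <- dimnames(signal) <- list(tgt_ids, feat)
    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(length(vals)) < config$missing_rate,
                     nrow(vals), ncol(vals))
      vals[drop] <- NA
    }
    meas <- measurement_table(vals, "metabolite")
    ceiling <- vapply(seq_len(n_cont), function(j) {
      stats::cor(vals[, j], signal[, j], method = "spearman",
                 use = "complete.obs")
    }, numeric(1))
    names(ceiling) <- feat
  }

  mut <- NULL; gamma <- NULL
  n_bin <- config$n_binary_features
  if (n_bin > 0) {
    gamma <- matrix(stats::rnorm(d * n_bin), d, n_bin)
    score <- Z_tgt %*% gamma
    bin <- vapply(seq_len(n_bin), function(j) {
      cut <- stats::quantile(score[, j], 1 - config$positive_rate, type = 7)
      as.numeric(score[, j] > cut)
    }, numeric(config$n_target))
    dimnames(bin) <- list(tgt_ids, sprintf("MUT%03d", seq_len(n_bin)))
    mut <- measurement_table(bin, "mutation")
  }

  list(
    source = expression_matrix(src),
    target = expression_matrix(tgt),
    measurements = meas,
    mutations = mut,
    truth = list(loadings = loadings, beta = beta, gamma = gamma,
                 shifted_genes = shifted, domain_offsets = domain_offsets,
                 Z_source = Z_src, Z_target = Z_tgt,
                 signal = signal, noise_ceiling = ceiling, config = config)
  )
}

#' Recovery report against the generator's ground truth
#'
#' Scores a feature-selection result (and optionally model metrics)
#' against the known truth of [generate_domains()]: precision and recall
#' of shifted-gene exclusion, and the predictive ceiling per continuous
#' feature.
#'
#' @param truth the `truth` record returned by [generate_domains()].
#' @param selection a `feature_selection` tibble from
#'   [select_similar_genes()].
#' @param model_spearman optional named vector of achieved test Spearman
#'   per feature, compared against the noise ceiling.
#' @return List with `exclusion_precision`, `exclusion_recall`,
#'   `n_excluded`, and a `features` tibble (`feature_id`,
#'   `noise_ceiling`, and `spearman`/`spearman_gap` when supplied).
#' @export
truth_recovery_report <- function(truth, selection, model_spearman = NULL) {
  stopifnot(inherits(selection, "feature_selection"))
  if (!all(truth$shifted_genes %in% selection$gene_id)) {
    stop("selection does not cover the generator's gene ids", call. = FALSE)
  }
  excluded <- selection$gene_id[!selection$selected]
  hits <- intersect(excluded, truth$shifted_genes)
  features <- tibble::tibble(feature_id = names(truth$noise_ceiling),
                             noise_ceiling = unname(truth$noise_ceiling))
  if (!is.null(model_spearman)) {
    if (!all(names(model_spearman) %in% features$feature_id)) {
      stop("model_spearman names do not match generated features", call. = FALSE)
    }
    features$spearman <- unname(model_spearman[features$feature_id])
    features$spearman_gap <- features$noise_ceiling - features$spearman
  }
  list(
    exclusion_precision = if (length(excluded)) length(hits) / length(excluded)
                          else NA_real_,
    exclusion_recall = if (length(truth$shifted_genes))
                         length(hits) / length(truth$shifted_genes) else NA_real_,
    n_excluded = length(excluded),
    features = features
  )
}
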