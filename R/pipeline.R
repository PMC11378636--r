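#' Total number of precomputed models across measurement types
#'
#' Each measurement feature gets one model per cross-validation fold, so
#' a portal serving `replicates_per_feature` fold models per feature
#' stores `sum(feature_counts) * replicates_per_feature` models in total.
#'
#' @param feature_counts non-negative integer vector, one entry per
#'   measurement type (number of features of that type).
#' @param replicates_per_feature models stored per feature (default 5,
#'   one per fold).
#' @return A single integer.
#' @export
#' @examples
#' count_models(c(225, 214, 18333, 4686, 27639, 19451), 5)
count_models <- function(feature_counts, replicates_per_feature = 5L) {
  if (length(feature_counts) == 0L) return(0L)
  if (any(is.na(feature_counts)) || any(feature_counts < 0) ||
      any(feature_counts != round(feature_counts))) {
    stop("feature_counts must be non-negative integers", call. = FALSE)
  }
  if (replicates_per_feature < 1) stop("replicates_per_feature must be >= 1",
                                       call. = FALSE)
  as.integer(sum(feature_counts) * replicates_per_feature)
}

#' Pipeline run configuration
#'
#' Bundles every stage's settings and seeds for [run_pipeline()].
#'
#' @param out_dir run directory (created if absent).
#' @param sim a [synthetic_config()] for the simulate stage.
#' @param k number of similar genes to select (default: all genes minus
#'   the configured number of shifted genes).
#' @param variant encoder provenance for the pretrain stage.
#' @param hidden_dim,bottleneck_dim autoencoder widths (desk-scale
#'   defaults 64/16).
#' @param pretrain,fit [train_config()]s for pre-training / fine-tuning.
#' @param head_config prediction-head settings.
#' @param cv_folds,cv_seed cross-validation protocol.
#' @param n_continuous,n_mutation numbers of continuous / binary features
#'   carried through the train stage (desk-scale defaults 2 and 1).
#' @param cap feature cap per type ([subsample_features()]).
#' @param screen_threshold activity cutoff for the screen stage.
#' @param n_groups number of cell-line groups (k-means on target
#'   expression) used in the screen stage.
#' @param f1_gate macro-F1 gate for serving mutation models.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       sim = synthetic_config(),
                       k = sim$n_genes - sim$n_shifted_genes,
                       variant = "two_step",
                       hidden_dim = 64L, bottleneck_dim = 16L,
                       pretrain = train_config(epochs = 40, patience = 10, seed = 1L),
                       fit = train_config(epochs = 40, patience = 10, seed = 1L),
                       head_config = list(hidden = c(32L, 16L)),
                       cv_folds = 5L, cv_seed = 1L,
                       n_continuous = 2L, n_mutation = 1L,
                       cap = 2000L,
                       screen_threshold = -2,
                       n_groups = 2L,
                       f1_gate = 0.7) {
  structure(as.list(environment()), class = "run_config")
}

.stage_files <- function(out_dir, files) file.path(out_dir, files)

.files_unchanged <- function(manifest, out_dir, stage) {
  rec <- manifest$stages[[stage]]
  if (is.null(rec)) return(FALSE)
  files <- .stage_files(out_dir, names(rec$md5))
  all(file.exists(files)) &&
    identical(unname(tools::md5sum(files)), unname(unlist(rec$md5)))
}

.record_stage <- function(manifest, out_dir, stage, files, extra = list()) {
  md5 <- as.list(tools::md5sum(.stage_files(out_dir, files)))
  names(md5) <- files
  manifest$stages[[stage]] <- c(list(completed = TRUE, md5 = md5), extra)
  manifest
}

#' Run the end-to-end pipeline on the synthetic scenario
#'
#' Executes the stages in order — simulate, select_features, pretrain,
#' train, evaluate, screen — persisting every artifact under `out_dir`:
#' the domain TSVs, the feature-selection table, the encoder weights, one
#' weight file per (feature, fold) in a registry laid out by measurement
#' type, the per-fold and aggregate results TSVs, and the screening
#' selectivity table. A JSON manifest records seeds, the config hash, and
#' the MD5 of every artifact; re-running over a finished directory with
#' `resume = TRUE` skips stages whose outputs are unchanged, making the
#' rerun a no-op.
#'
#' @param config a [run_config()].
#' @param resume skip stages whose recorded outputs are intact (default
#'   `TRUE`).
#' @return The manifest (invisibly), a list describing each completed
#'   stage.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  cfg_json <- jsonlite::serializeJSON(config[setdiff(names(config), "out_dir")])
  manifest <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list(stages = list())
  cfg_hash <- as.character(.md5_string(cfg_json))
  if (!is.null(manifest$config_hash) && !identical(manifest$config_hash, cfg_hash)) {
    manifest <- list(stages = list())  # config changed: start over
  }
  manifest$config_hash <- cfg_hash
  manifest$seeds <- list(sim = config$sim$seed, pretrain = config$pretrain$seed,
                         fit = config$fit$seed, cv = config$cv_seed)
  save_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <- list(completed = FALSE,
                                     error = conditionMessage(e))
    save_manifest()
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  ## 1. simulate ------------------------------------------------------
  sim_files <- c("source.tsv", "target.tsv", "measurements.tsv", "mutations.tsv")
  if (!(resume && .files_unchanged(manifest, out_dir, "simulate"))) {
    tryCatch({
      dom <- generate_domains(config$sim)
      write_expression(dom$source, file.path(out_dir, "source.tsv"))
      write_expression(dom$target, file.path(out_dir, "target.tsv"))
      write_measurements(dom$measurements, file.path(out_dir, "measurements.tsv"))
      write_measurements(dom$mutations, file.path(out_dir, "mutations.tsv"))
      jsonlite::write_json(
        list(shifted_genes = dom$truth$shifted_genes,
             noise_ceiling = as.list(dom$truth$noise_ceiling)),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      manifest <- .record_stage(manifest, out_dir, "simulate",
                                c(sim_files, "truth.json"))
      save_manifest()
    }, error = function(e) fail("simulate", e))
  }
  source_expr <- read_expression(file.path(out_dir, "source.tsv"), "samples")
  target_expr <- read_expression(file.path(out_dir, "target.tsv"), "samples")
  measurements <- read_measurements(file.path(out_dir, "measurements.tsv"),
                                    "metabolite")
  mutations <- read_measurements(file.path(out_dir, "mutations.tsv"), "mutation")

  ## 2. select_features ----------------------------------------------
  if (!(resume && .files_unchanged(manifest, out_dir, "select_features"))) {
    tryCatch({
      sel <- select_similar_genes(source_expr, target_expr, k = config$k)
      utils::write.table(sel, file.path(out_dir, "selection.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest <- .record_stage(manifest, out_dir, "select_features",
                                "selection.tsv")
      save_manifest()
    }, error = function(e) fail("select_features", e))
  }
  sel <- utils::read.table(file.path(out_dir, "selection.tsv"), header = TRUE,
                           sep = "\t")
  genes <- sel$gene_id[sel$selected]

  ## 3. pretrain ------------------------------------------------------
  if (!(resume && .files_unchanged(manifest, out_dir, "pretrain"))) {
    tryCatch({
      spec <- autoencoder_spec(length(genes), config$hidden_dim,
                               config$bottleneck_dim)
      enc <- make_encoder_variant(unclass(source_expr)[, genes, drop = FALSE],
                                  unclass(target_expr)[, genes, drop = FALSE],
                                  spec, variant = config$variant,
                                  config = config$pretrain)
      save_weights(enc, file.path(out_dir, "encoder.rds"))
      manifest <- .record_stage(manifest, out_dir, "pretrain", "encoder.rds",
                                extra = list(provenance = enc$provenance))
      save_manifest()
    }, error = function(e) fail("pretrain", e))
  }
  encoder <- load_weights(file.path(out_dir, "encoder.rds"))

  ## 4. train ---------------------------------------------------------
  cont_feats <- subsample_features(colnames(measurements), config$cap,
                                   config$cv_seed)
  cont_feats <- utils::head(cont_feats, config$n_continuous)
  mut_feats <- utils::head(subsample_features(colnames(mutations), config$cap,
                                              config$cv_seed),
                           config$n_mutation)
  if (!(resume && .files_unchanged(manifest, out_dir, "train"))) {
    tryCatch({
      reg <- file.path(out_dir, "registry")
      evals <- list()
      train_one <- function(meas, feats, type, task_kind) {
        type_dir <- file.path(reg, type)
        dir.create(type_dir, showWarnings = FALSE, recursive = TRUE)
        lapply(feats, function(f) {
          task <- align_task(target_expr, meas, f, genes)
          factory <- function(X, y, fold_seed) {
            fc <- config$fit; fc$seed <- fold_seed
            m <- build_predictor(encoder, task_kind,
                                 head_config = config$head_config)
            fit_predictor(m, X, y, config = fc)
          }
          ev <- run_cv(task, factory, k = config$cv_folds,
                       seed = config$cv_seed, method_label = "transfer")
          for (fold in seq_len(config$cv_folds)) {
            save_weights(ev$models[[fold]],
                         file.path(type_dir,
                                   sprintf("%s_fold%d.rds", f, fold)))
          }
          ev
        })
      }
      evals <- c(train_one(measurements, cont_feats, "metabolite", "regression"),
                 train_one(mutations, mut_feats, "mutation", "classification"))
      per_fold <- dplyr::bind_rows(lapply(evals, tidy))
      aggregates <- dplyr::bind_rows(lapply(evals, glance))
      oof <- dplyr::bind_rows(lapply(evals, function(e)
        dplyr::mutate(e$predictions, feature_id = e$feature_id)))
      utils::write.table(per_fold, file.path(out_dir, "results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(aggregates, file.path(out_dir, "aggregates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(oof, file.path(out_dir, "predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      reg_files <- file.path("registry",
                             list.files(reg, recursive = TRUE))
      manifest <- .record_stage(manifest, out_dir, "train",
                                c("results.tsv", "aggregates.tsv",
                                  "predictions.tsv", reg_files))
      save_manifest()
    }, error = function(e) fail("train", e))
  }

  ## 5. evaluate ------------------------------------------------------
  if (!(resume && .files_unchanged(manifest, out_dir, "evaluate"))) {
    tryCatch({
      agg <- utils::read.table(file.path(out_dir, "aggregates.tsv"),
                               header = TRUE, sep = "\t")
      rmse_rows <- agg[agg$metric == "rmse", ]
      partition <- if (nrow(rmse_rows) >= 4L) {
        quartile_partition(stats::setNames(rmse_rows$mean, rmse_rows$feature_id))
      } else list(well = character(0), poor = character(0),
                  q1 = NA_real_, q3 = NA_real_)
      f1_rows <- agg[agg$metric == "f1_macro", ]
      served <- f1_rows$feature_id[f1_rows$mean > config$f1_gate]
      jsonlite::write_json(
        list(well = partition$well, poor = partition$poor,
             q1 = partition$q1, q3 = partition$q3,
             served_mutation_features = served, f1_gate = config$f1_gate),
        file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
      manifest <- .record_stage(manifest, out_dir, "evaluate", "evaluation.json")
      save_manifest()
    }, error = function(e) fail("evaluate", e))
  }

  ## 6. screen --------------------------------------------------------
  if (!(resume && .files_unchanged(manifest, out_dir, "screen"))) {
    tryCatch({
      oof <- utils::read.table(file.path(out_dir, "predictions.tsv"),
                               header = TRUE, sep = "\t")
      oof <- oof[oof$feature_id %in% cont_feats, ]
      set.seed(config$cv_seed)
      km <- stats::kmeans(unclass(target_expr)[, genes, drop = FALSE],
                          centers = config$n_groups, nstart = 5)
      grp <- tibble::tibble(cell_line = rownames(target_expr),
                            group = paste0("grp", km$cluster))
      screen <- oof |>
        dplyr::transmute(cell_line = .data$sample_id, drug = .data$feature_id,
                         score = .data$predicted) |>
        dplyr::inner_join(grp, by = "cell_line")
      selectivity <- dplyr::bind_rows(lapply(unique(grp$group), function(g)
        drug_selectivity(screen, g, threshold = config$screen_threshold)))
      utils::write.table(selectivity, file.path(out_dir, "selectivity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest <- .record_stage(manifest, out_dir, "screen", "selectivity.tsv")
      save_manifest()
    }, error = function(e) fail("screen", e))
  }
  save_manifest()
  invisible(manifest)
}

# md5 of an in-memory string, via a temporary file
.md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

#' Ensemble prediction from a pipeline registry
#'
#' Loads the `n_folds` fold models stored for one feature and returns the
#' per-sample mean of their predictions. When `gate` is supplied and the
#' registry's run directory records a macro F1 at or below the gate for a
#' mutation feature, the feature is refused as not served.
#'
#' @param registry_path the `registry/` directory of a [run_pipeline()]
#'   run (or the run directory itself).
#' @param feature_id the measurement feature.
#' @param X numeric matrix of selected-gene expression (columns must
#'   match the encoder input).
#' @param n_folds expected replicate count (default 5).
#' @param gate optional macro-F1 gate for mutation features (e.g. 0.7).
#' @return Numeric vector of ensemble predictions.
#' @export
predict_ensemble <- function(registry_path, feature_id, X, n_folds = 5L,
                             gate = NULL) {
  if (basename(registry_path) != "registry" &&
      dir.exists(file.path(registry_path, "registry"))) {
    registry_path <- file.path(registry_path, "registry")
  }
  hits <- list.files(registry_path, recursive = TRUE, full.names = TRUE,
                     pattern = paste0("^", feature_id, "_fold[0-9]+\\.rds$"))
  expected <- sprintf("%s_fold%d.rds", feature_id, seq_len(n_folds))
  missing <- setdiff(expected, basename(hits))
  if (length(missing)) {
    stop("missing replicate model file(s) for ", feature_id, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(gate)) {
    agg_path <- file.path(dirname(registry_path), "aggregates.tsv")
    if (file.exists(agg_path)) {
      agg <- utils::read.table(agg_path, header = TRUE, sep = "\t")
      f1 <- agg[agg$feature_id == feature_id & agg$metric == "f1_macro", ]
      if (nrow(f1) && all(f1$mean <= gate)) {
        stop("feature ", feature_id, " is gated out (macro F1 ",
             signif(f1$mean[1], 3), " <= ", gate, ")", call. = FALSE)
      }
    }
  }
  hits <- hits[match(expected, basename(hits))]
  X <- as.matrix(X)
  preds <- sapply(hits, function(p) as.numeric(predict(load_weights(p), X)))
  rowMeans(matrix(preds, nrow = nrow(X)))
}
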