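small_cfg <- function(...) {
  synthetic_config(n_source = 120L, n_target = 80L, n_genes = 40L,
                   n_shifted_genes = 4L, latent_dim = 4L,
                   n_continuous_features = 5L, n_binary_features = 3L, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  a <- generate_domains(small_cfg(seed = 5L))
  b <- generate_domains(small_cfg(seed = 5L))
  expect_identical(unclass(a$source), unclass(b$source))
  expect_identical(unclass(a$target), unclass(b$target))
  expect_identical(unclass(a$measurements), unclass(b$measurements))
  expect_identical(a$truth$shifted_genes, b$truth$shifted_genes)

  c_ <- generate_domains(small_cfg(seed = 6L))
  expect_false(identical(unclass(a$source), unclass(c_$source)))
})

test_that("generated matrices are complete; missingness only where configured", {
  dom <- generate_domains(small_cfg(seed = 2L))
  expect_false(anyNA(dom$source))
  expect_false(anyNA(dom$target))
  expect_false(anyNA(dom$measurements))

  dom_miss <- generate_domains(small_cfg(seed = 2L, missing_rate = 0.2))
  frac <- mean(is.na(dom_miss$measurements))
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.3)
  expect_false(anyNA(dom_miss$mutations))
})

test_that("binary features hit the configured positive rate", {
  dom <- generate_domains(synthetic_config(n_target = 400L, n_source = 50L,
                                           n_genes = 30L, n_shifted_genes = 0L,
                                           n_binary_features = 6L,
                                           positive_rate = 0.2, seed = 3L))
  rates <- colMeans(unclass(dom$mutations))
  # 3 binomial SDs at n = 400
  expect_true(all(abs(rates - 0.2) < 3 * sqrt(0.2 * 0.8 / 400) + 0.01))
})

test_that("strongly shifted genes fall to the bottom of the similarity ranking", {
  cfg <- synthetic_config(n_source = 300L, n_target = 300L, seed = 4L)
  dom <- generate_domains(cfg)
  sel <- select_similar_genes(dom$source, dom$target,
                              k = cfg$n_genes - cfg$n_shifted_genes)
  bottom <- sel$gene_id[!sel$selected]
  expect_setequal(bottom, dom$truth$shifted_genes)
})

test_that("with all shift knobs at zero the raw KS p-values are calibrated", {
  # shared latent factors correlate the per-gene p-values, so the binomial
  # band only applies when genes are noise-dominated and effectively
  # independent; 1000 genes tighten the band
  cfg <- synthetic_config(n_source = 300L, n_target = 300L,
                          shift_magnitude = 0, n_shifted_genes = 0L,
                          domain_shift_sd = 0, n_genes = 1000L,
                          latent_dim = 1L, loading_scale = 0.01, noise_sd = 1,
                          n_continuous_features = 0L, n_binary_features = 0L,
                          seed = 1L)
  dom <- generate_domains(cfg)
  sel <- select_similar_genes(dom$source, dom$target, k = 1000L)
  frac <- mean(sel$p_raw < 0.05)
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("the noise ceiling decreases with measurement noise", {
  ceilings <- sapply(c(0.1, 0.5, 1, 2, 5), function(ns) {
    dom <- generate_domains(small_cfg(seed = 7L, target_noise_sd = ns))
    mean(dom$truth$noise_ceiling)
  })
  expect_true(all(diff(ceilings) < 0))
  # very large noise drives the achievable correlation toward zero
  dom_inf <- generate_domains(small_cfg(seed = 7L, target_noise_sd = 50))
  expect_lt(mean(abs(dom_inf$truth$noise_ceiling)), 0.2)
})

test_that("truth recovery scores exclusion and the predictive ceiling", {
  cfg <- synthetic_config(n_source = 300L, n_target = 300L, n_genes = 40L,
                          n_shifted_genes = 4L, latent_dim = 4L,
                          n_continuous_features = 5L, n_binary_features = 3L,
                          seed = 8L)
  dom <- generate_domains(cfg)
  sel <- select_similar_genes(dom$source, dom$target,
                              k = cfg$n_genes - cfg$n_shifted_genes)
  rpt <- truth_recovery_report(dom$truth, sel)
  expect_equal(rpt$exclusion_recall, 1)
  expect_equal(rpt$exclusion_precision, 1)
  expect_equal(rpt$n_excluded, 4L)

  # a predictor equal to the noiseless component attains the ceiling
  f1 <- rpt$features$feature_id[1]
  rho <- spearman_cor(unclass(dom$measurements)[, f1], dom$truth$signal[, f1])
  expect_equal(rho, rpt$features$noise_ceiling[1])

  bad_sel <- sel
  bad_sel$gene_id <- paste0("X", bad_sel$gene_id)
  expect_error(truth_recovery_report(dom$truth, bad_sel), "gene ids")
})

test_that("spearman gaps are reported when model metrics are supplied", {
  dom <- generate_domains(small_cfg(seed = 9L))
  sel <- select_similar_genes(dom$source, dom$target, k = 36L)
  achieved <- setNames(rep(0.5, 2), colnames(dom$measurements)[1:2])
  rpt <- truth_recovery_report(dom$truth, sel, model_spearman = achieved)
  f <- rpt$features
  expect_equal(f$spearman[f$feature_id %in% names(achieved)], c(0.5, 0.5))
  expect_equal(f$spearman_gap, f$noise_ceiling - f$spearman)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_shifted_genes = 50L, n_genes = 40L))
  expect_error(synthetic_config(positive_rate = 0))
  expect_error(synthetic_config(positive_rate = 1.2))
})
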