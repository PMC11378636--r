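# cellbridge

Predicting molecular measurements of cancer cell lines — metabolite
abundance, protein levels, copy number, CRISPR gene-dependency scores,
drug sensitivity, mutation status — from bulk gene expression
(`log2(1 + TPM)`) alone, using cross-domain transfer learning. The
package is aimed at groups who can afford RNA-seq of new or modified
cell lines but not the panel of downstream assays, and at
methodologists benchmarking expression-only predictors.

## The method

Cell-line panels are small (hundreds of lines per measurement) while
tumor compendia are large (~10,000 expression profiles), so the package
transfers representation from tumors to cell lines in three steps:

1. **Domain-similarity feature selection.** Per shared gene, a
   two-sample Kolmogorov–Smirnov test
   `D_g = sup_t |F_src(t) − F_tgt(t)|` with asymptotic p, BH-adjusted;
   the `k` genes with the *largest* adjusted p (most compatible
   distributions) are kept, which protects the transfer from genes whose
   domain shift would inject noise into the target model ("negative
   transfer").
2. **Two-step autoencoder pre-training.** An autoencoder
   `h = LeakyReLU(Wx + b)`, `x̂ = W'h + b'` minimizing
   `(1/n) Σ ||x_i − x̂_i||²` is trained on the source domain, its encoder
   weights are copied in as the initialization of a second autoencoder
   trained on the target domain, and the refined encoder (genes → 512 →
   200 at production scale) is extracted.
3. **Fine-tuned prediction.** A 4-layer feedforward head on the
   bottleneck; all layers fine-tune per measurement feature (MSE for
   continuous targets, cross-entropy for mutation), evaluated by
   five-fold cross-validation with mean ± 95% CI of MSE, RMSE and
   Spearman (AUC/F1 for mutation).

A baseline suite (lasso, elastic net, random forest, their logistic
counterparts, PCA + DNN, and the same architecture without
pre-training), a quartile-based well/poor feature partition, a
drug-screening selectivity analysis (active = predicted score < −2,
Fisher exact test per cancer group), and a synthetic two-domain
generator with known ground truth round out the package. Everything
runs on one CPU; no deep-learning backend is required.

## Worked example

Simulate paired domains, select compatible genes, pre-train with
transfer, and cross-validate one metabolite model:

```r
library(cellbridge)

cfg <- synthetic_config(n_source = 500L, n_target = 250L, seed = 42L)
dom <- generate_domains(cfg)

sel <- select_similar_genes(dom$source, dom$target, k = 270)
sel
#> # A tibble: 300 × 6
#>   gene_id ks_statistic p_raw p_adjusted  rank selected
#>   <chr>          <dbl> <dbl>      <dbl> <int> <lgl>
#> 1 G0079          0.038 0.970      0.970     1 TRUE
#> 2 G0218          0.038 0.970      0.970     2 TRUE
#> 3 G0081          0.04  0.952      0.959     3 TRUE
truth_recovery_report(dom$truth, sel)$exclusion_recall
#> [1] 1        # all 30 planted distribution-shifted genes were rejected

genes <- selected_genes(sel)
spec <- autoencoder_spec(length(genes), 64L, 16L)
enc <- two_step_pretrain(unclass(dom$source)[, genes],
                         unclass(dom$target)[, genes],
                         spec, config = train_config(epochs = 40, seed = 1))
enc
#> <encoder_state> 270 -> 64 -> 16 (provenance: two_step)

task <- align_task(dom$target, dom$measurements, "M001", genes)
factory <- function(X, y, fold_seed) {
  m <- build_predictor(enc, "regression", head_config = list(hidden = c(32, 16)))
  fit_predictor(m, X, y, config = train_config(epochs = 30, patience = 10,
                                               seed = fold_seed))
}
ev <- run_cv(task, factory, seed = 1, method_label = "transfer")
ev
#> <cv_evaluation> feature M001, method transfer, 5 folds
#> # A tibble: 3 × 5
#>   metric    mean lower upper     n
#>   <chr>    <dbl> <dbl> <dbl> <int>
#> 1 mse      0.731 0.541 0.922     5
#> 2 rmse     0.851 0.736 0.966     5
#> 3 spearman 0.942 0.916 0.967     5
```

The Spearman of 0.94 reads against the feature's noise ceiling (the rank
correlation a perfect model of the noiseless signal would attain,
reported by `truth_recovery_report()`); the mean/lower/upper columns are
the five-fold mean with its t-based 95% CI. `autoplot(ev)`,
`autoplot(sel)` and `plot_training_history(enc)` draw the standard
diagnostics; `run_pipeline()` chains all stages (simulate → select →
pretrain → train → evaluate → screen) into a run directory with a
manifest, a per-(feature, fold) model registry, and
`predict_ensemble()` serving fold-averaged predictions.

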