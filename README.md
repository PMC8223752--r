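# rascore

Cross-tissue transcriptomic biomarker discovery for rheumatoid arthritis
(RA), packaged as a tested, reusable pipeline. Starting from multiple
gene-expression datasets of synovial biopsy and whole-blood samples, the
package:

1. **preprocesses** each study (log2 scale, intra-study quantile
   normalization), merges studies on their common genes and removes
   dataset-of-origin batch effects with a parametric empirical-Bayes
   location/scale adjustment (ComBat-style), imputing missing sex
   annotations from mean Y-chromosome expression;
2. fits **covariate-adjusted differential expression** per gene with
   empirical-Bayes moderated t-statistics (posterior variance
   s̃²ᵍ = (d₀s₀² + dᵍs²ᵍ)/(d₀ + dᵍ), prior (d₀, s₀²) estimated by moment
   matching on log variances), calling genes at FDR < 0.05 and
   fold change > 1.2, and tests cross-tissue overlaps with an exact
   hypergeometric tail;
3. runs an **iterative resampling feature-selection loop**: stratified
   80:20 splits per tissue, training-set significance (BH < 0.05),
   a point-biserial status-correlation filter (|r| ≥ 0.25), greedy
   redundancy pruning (pairwise |r| ≤ 0.8, strongest gene kept),
   cross-tissue intersection under a co-directionality constraint, and a
   per-gene held-out logistic-regression AUROC; genes present in every
   iteration with mean test AUROC > 2/3 in **both** tissues survive;
4. **validates** each surviving gene on independent cohorts (one
   discovery fit, applied unchanged; mean validation AUROC > 0.8) and
   combines the validated panel into the **RA Score**

   RA Score(sample) = GM(up-regulated panel genes) − GM(down-regulated panel genes),

   the difference of geometric means on the linear expression scale
   (GM = 2^mean(log₂ x)), with a clinical association battery: group
   effects, per-dataset DAS28 correlations pooled with a bootstrap CI,
   Fisher-combined p-values, bootstrap odds ratios per 1 SD of score, and
   a random-panel null distribution;
5. provides **batch diagnostics**: multinomial log loss of a random
   forest predicting dataset of origin from the leading principal
   components (higher loss = better mixing), per-PC Kruskal–Wallis tests
   against batch, and label-free k-means cluster evaluation of gene
   subsets.

Because the real GEO compendium is outside desk scale, the package ships a
**synthetic compendium generator** (`sim_config()`, `generate_compendium()`)
that emulates the statistical structure of such a collection — multiple
datasets per tissue with additive/multiplicative batch effects, a planted
co-directional disease signal (stronger in synovium than blood), correlated
gene blocks, Y-driven sex signal, treatment attenuation, OA/polyJIA-like
contrast groups, DAS28 tied to a latent disease burden, and blood class
imbalance — together with a ground-truth record so every stage can be
scored against the generating model.

## Worked example

```r
library(rascore)

cfg <- sim_config(seed = 1)                      # default study conditions
sim <- generate_compendium(cfg)

prep <- function(studies) {
  studies <- lapply(studies, function(s) {
    s$values <- quantile_normalize(s$values); s
  })
  combat_adjust(merge_studies(studies))$values
}
synovium <- prep(sim$studies$synovium)
blood    <- prep(sim$studies$blood)

fs <- run_feature_selection(synovium, blood,
                            fs_config(n_iterations = 25, base_seed = 1001))
fs
#> fs_report: 25 iterations over 2000 common genes
#>   always selected: 53 genes; final (AUC > 0.667 in both tissues): 53

planted <- c(sim$truth$planted_up, sim$truth$planted_down)
mean(planted %in% fs$final_genes)   # sensitivity vs ground truth
#> [1] 0.8833333
mean(fs$final_genes %in% planted)   # precision
#> [1] 1

panel <- list(up_genes = sim$truth$planted_up,
              down_genes = sim$truth$planted_down)
m  <- merge_studies(sim$studies$blood)
sc <- ra_score(m, panel)            # per-sample geometric-mean difference
cc <- m$annotations$status %in% c("case", "control")
score_group_effect(sc[cc], m$annotations$status[cc])$p
#> [1] 8.169373e-132
```

The feature selection recovers 53 of the 60 planted co-directional genes
with no false positives; the composite score separates cases from controls
decisively. The two printed fractions are sensitivity and precision
against the generator's ground truth.

An end-to-end driver, `run_pipeline(pipeline_config(), out_dir)`, chains
simulation, preprocessing, differential expression, feature selection,
validation on independently simulated cohorts, scoring and diagnostics,
writing every intermediate table plus a `summary.json`.

## Layout

- `R/` — simulation, preprocessing, batch adjustment, differential
  expression, feature selection, validation/scoring, diagnostics, I/O and
  the pipeline driver
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (exhaustive AUROC pair counting, hypergeometric
  enumeration, straight-line EB batch adjustment, brute-force BH)
- `vignettes/cross-tissue-scoring.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations
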