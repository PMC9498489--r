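# boxlasso

Two-stage machine-learning feature selection for case-control RNA-seq count
data, aimed at transcriptomics researchers who want stable, interpretable
gene shortlists rather than black-box classifiers. The package was built
around whole-blood inflammatory bowel disease (IBD / ulcerative colitis /
Crohn's disease vs control) cohorts, but any binary contrast over a gene ×
sample count matrix fits.

## The method

Starting from raw counts `c[i, j]` (gene *i*, sample *j*):

1. **Filter & normalize.** Remove genes with total count ≤ 10; compute
   median-of-ratios size factors
   `s_j = median_i c[i,j] / (prod_v c[i,v])^(1/m)`; transform to
   `x[i,j] = log2(c[i,j]/s_j + 1)` so zero counts stay exactly zero.
2. **PCA preselection.** Scale genes to unit variance, run PCA over the
   contrast's samples and, per principal component (first 3), keep the
   shortest prefix of genes whose squared loadings reach 95% of that
   component's loading mass; take the union.
3. **Box-constrained binomial lasso.** Minimize
   `(1/n) Σ[-y η + log(1+e^η)] + λ‖β‖₁` subject to `-0.1 ≤ β_j ≤ 0.1`
   (intercept free), by IRLS with cyclic coordinate descent where every
   coordinate update is a soft-threshold clipped to the box.
4. **Cross-validated λ grid.** λ = 0.01 … 0.40 (by 0.01) × stratified
   ten-fold cross-validation, warm starts, held-out Mann-Whitney AUC.
   Per λ, the median AUC over folds with AUC > 0.5 is computed; the selected
   λ is the largest within 0.01 of the best median (strongest shrinkage at
   essentially no loss of precision).
5. **Stability scoring.** Every transcript's *occurrence count n*: the
   number of the 400 (fold, λ) models in which it is active. The final
   model is refit on all samples at the selected λ and reported with the
   cross-validated AUC and a 90% fold-percentile confidence interval.

A negative-binomial simulator (`simulate_dataset()`) generates cohorts with
library-size variation, planted differential genes and correlated
co-expression blocks, so the entire pipeline can be exercised and validated
without external data. See the vignette
(`vignettes/two-stage-feature-selection.Rmd`) for the modelling decisions
and their rationale.

## Worked example

```r
library(boxlasso)

ds  <- simulate_dataset(simulation_spec(n_genes = 500, n_cases = 60,
                                        n_controls = 60, n_signal_genes = 10,
                                        seed = 2024))
cfg <- pipeline_config(rng_seed = 2024)
rep <- run_pipeline(ds$counts, ds$samples, cfg,
                    contrasts = "IBD_vs_control")$IBD_vs_control
rep
#> cv_report: lambda = 0.36, AUC = 1.00 (0.79-1.00), 2 genes in model
head(rep$model_table)
#>         gene coefficient occurrence_n
#> 1 gene_00458  0.06265922          370
#> 2 gene_00370  0.02611434          363
```

Both reported genes are planted signal genes (`ds$signal_genes`). Reading
the output: the selected penalty λ = 0.36 is strong, so the final model
keeps only two complementary transcripts; their occurrence counts (370 and
363 of a possible 400 fold × λ models) mark them as highly stable
selections; the AUC of 1.00 with 90% CI (0.79–1.00) is the median and the
5th/95th percentiles of the ten held-out fold AUCs at the selected λ.

`write_report(rep, "out/IBD_vs_control")` writes `model.tsv`, `cv.tsv` and
`summary.json`; `run_all()` iterates the twelve built-in contrasts (IBD/UC/CD
vs control overall and by age group, plus active-disease contrasts) and adds
a gene × contrast occurrence matrix. A thin command-line wrapper is at
`inst/cli/boxlasso.R` (`simulate`, `run`, `run-all`).

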