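---
title: "Two-stage feature selection for case-control transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage feature selection for case-control transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(boxlasso.quiet = TRUE)
```

# The problem

Whole-blood RNA-seq case-control cohorts (here: inflammatory bowel disease —
ulcerative colitis and Crohn's disease — against healthy controls) carry
diagnostic signal spread across many correlated transcripts. A classifier
built directly on ten thousand genes with a couple of hundred samples
overfits; a univariate differential-expression screen returns whole
co-expression modules of redundant hits. `boxlasso` implements a two-stage
selection strategy that addresses both problems:

1. **Unsupervised preselection.** Principal component analysis over the
   scaled genes summarizes the dominant co-expression structure; transcripts
   carrying most of the loading mass of the first few components are kept.
   This both reduces dimensionality and, because each small-scale cluster of
   co-expression is represented by its highest-loading members, reduces
   collinearity before the supervised stage.
2. **Sparse supervised selection.** Box-constrained L1-penalized (lasso)
   logistic regression over a grid of penalties, inside ten-fold
   cross-validation. The per-coefficient box keeps any single transcript
   from dominating, so models are forced to spread weight over several
   complementary genes. Stability is scored by counting, for every
   transcript, the number of (fold, penalty) models in which it is active.

The package also ships a negative-binomial count simulator so that the whole
pipeline is exercisable and testable without access to any particular cohort.

# Preprocessing

Genes whose **total count** across all samples is at most 10 are removed.
The phrase "expression at most 10" admits per-sample or mean readings; the
total-count reading is the loosest prefilter of the three and is therefore
the default, with the threshold exposed as `filter_threshold`.

Size factors use the **median-of-ratios** estimator: sample $j$ gets
$s_j = \operatorname{median}_i \, c_{ij} / (\prod_v c_{iv})^{1/m}$ over the
genes $i$ with strictly positive counts everywhere (genes containing a zero
are excluded from the reference set). Size factors are computed on the
post-filter matrix, matching the stage order of the pipeline.

The normalized value is
$$x_{ij} = \log_2\!\left(\frac{c_{ij}}{s_j} + 1\right).$$
The order — divide, add the offset 1, then log — is the only one for which a
zero count maps to exactly zero on the transformed scale, which the pipeline
treats as a hard invariant ("zeros stay null"). `log_offset` is
configurable; values other than 1 lose the exact-zero property.

# PCA preselection

Genes are centred and scaled to unit standard deviation ($n-1$ denominator;
zero-variance genes are dropped with a warning), and a PCA is run with
samples as observations and genes as variables, via SVD. Determinism across
linear-algebra backends is ensured by fixing each component's sign so that
its largest-magnitude loading is positive.

"Transcripts explaining 95% of the variance in the first three components"
is operationalized per component as **squared-loading mass**: genes are
ranked by squared loading and the shortest prefix reaching 95% of that
component's total squared-loading mass (which is exactly 1 for unit-norm
loadings) is selected; the final set is the union over the first
`n_pcs = 3` components. Squared loadings are the standard sign-invariant
"contribution" measure, and a per-gene sample-space variance reading would
not define a gene ranking at all. Ties in squared loading are broken by
input gene order.

Two scope choices were genuinely open:

* **Which samples enter the PCA.** The default is all samples of the
  contrast (cases and controls), since the analysis subset of a contrast is
  its case-control cohort; `pca_cases_only = TRUE` restricts to cases.
* **When the PCA runs.** By default once per contrast, before
  cross-validation — the conventional ordering for this kind of analysis,
  in which the preselection sees the held-out samples (an unsupervised,
  label-free leak, but a leak nonetheless). `nested_preselection = TRUE`
  re-runs the preselection inside every training fold for a fully
  leakage-free estimate. The flag exists because the two estimates can
  differ on weak signals.

Note that with diffuse noise loadings the 95% mass prefix keeps a large
fraction of genes (typically 60–85% on the simulated cohorts); the stage is
a soft filter, not a hard screen — most of the dimensionality reduction is
delegated to the lasso.

# Box-constrained binomial lasso

For labels $y_i \in \{0,1\}$ and standardized features $x_i$, the fit
minimizes
$$\frac{1}{n}\sum_i \left[-y_i \eta_i + \log(1 + e^{\eta_i})\right]
  + \lambda \lVert\beta\rVert_1
  \quad \text{s.t.} \quad L \le \beta_j \le U,$$
with $\eta_i = \beta_0 + x_i^\top \beta$ and the intercept unpenalized and
unconstrained. Defaults $L = -0.1$, $U = 0.1$, pure lasso ($\alpha = 1$).

The solver is iteratively reweighted least squares (IRLS) with cyclic
coordinate descent on the weighted quadratic subproblem. Each coordinate
update is the soft-threshold solution clipped to the box — exact for the
one-dimensional convex subproblem. Numerical safeguards:

* IRLS weights floored at $10^{-5}$ (the working response uses the floored
  weight consistently, so the fixed point still satisfies the exact
  first-order conditions);
* step-halving toward the previous iterate whenever the true objective
  would increase, making the objective non-increasing across accepted outer
  iterations;
* convergence requires both a maximum coefficient change below `coef_tol`
  ($10^{-7}$) and a Karush-Kuhn-Tucker (KKT) residual below `kkt_tol`
  ($10^{-6}$); budgets of 200 outer and 10,000 coordinate iterations.
  Non-convergence warns and flags the fit rather than erroring.
* sweeps visit features in fixed input order, with an active-set
  acceleration (full sweeps certify, active-set sweeps iterate), so results
  are platform-deterministic.

The KKT certificate checks, with $g_j = \tfrac1n x_j^\top(p - y)$: zero
coefficients need $|g_j| \le \lambda$; interior nonzero coefficients need
$g_j + \lambda\,\mathrm{sign}(\beta_j) = 0$; coefficients at a bound are
violated only if the subgradient points inward. `lambda_max` returns
$\max_j |\tfrac1n x_j^\top (y - \bar y)|$, above which the zero vector is
optimal.

Coefficients are bounded and reported on the **standardized-predictor
scale**: bounding only makes sense when it acts on comparably scaled
features, and published tables in this analysis style indeed show many
coefficients pinned at a common magnitude. The original-scale convention of
general-purpose penalized-regression software is the documented alternative.
The bounds are plain configuration (`coef_lower`, `coef_upper`, default
±0.1), so variants such as ±0.05 — which some published tables suggest —
are a one-line change.

# Cross-validation, lambda selection, stability

Folds are **stratified** (per-fold class counts within one of proportional)
— without stratification the small active-disease classes would routinely
produce one-class test folds. Standardization parameters are estimated on
each fold's training samples only and applied to the held-out fold. The
penalty grid is fitted per fold from the largest to the smallest $\lambda$
with warm starts.

Held-out performance is the Mann-Whitney AUC (ties count one half), so an
empty model with constant scores sits at exactly 0.5.

**Lambda selection:** per $\lambda$, the median held-out AUC is taken over
the folds with AUC strictly above `auc_null_cutoff = 0.5` (a $\lambda$ with
no qualifying folds is ineligible, as are non-converged fits). The selected
$\lambda$ is the **largest** eligible one whose median is within
`lambda_tolerance = 0.01` of the best median — the direct analogue of the
one-standard-error convention, realizing the precision/shrinkage tradeoff
as a deterministic rule.

**Occurrence counts:** for every transcript, the number of (fold, $\lambda$)
models — $10 \times 40 = 400$ at the defaults — in which it has a nonzero
coefficient ($|\beta_j| > 10^{-8}$). Non-converged fits are excluded from
lambda selection but still counted here, since the stability tally is
defined across all models. The ceiling is therefore 400; published counts
near 300 for top genes are consistent with transcripts active over most of
the eligible grid.

**Final report:** the model is refit on all contrast samples at the selected
$\lambda$; the table lists active genes sorted by coefficient (strongest
positive at top, strongest negative at bottom) with occurrence counts. The
reported AUC is the **median of held-out fold AUCs** at the selected
$\lambda$ — a cross-validated estimate, not the resubstitution AUC of the
refit — with a fold-percentile interval at `ci_level = 0.90` (5th/95th
percentiles of the ten fold AUCs). Percentiles of ten values are a coarse
but assumption-free interval; with ten folds the bounds land on order
statistics.

# Contrasts

Twelve built-ins: {IBD, UC, CD} vs control in all participants, adults and
children (nine), and active disease vs grouped controls-plus-remission
overall, in UC and in CD (three). On the 0-4 activity scale, grades 3-4 are
"active" and 0-1 "remission"; grade 2 is excluded from active contrasts by
default (`grade2_policy` can reassign it) since the scale's midpoint is not
clearly either. Controls always carry grade 0.

# The synthetic cohort generator

`simulate_dataset()` draws counts as
$$c_{ij} \sim \mathrm{NB}\!\left(\mu = s_j\, 2^{\,m_i + \Delta_i
\cdot \mathrm{case}_j + b_{ij}},\ \mathrm{Var} = \mu + \phi\mu^2\right)$$
with log-normal size factors $s_j$, uniform per-gene baselines $m_i$ on the
log2 scale, a planted log2 fold change $\Delta_i$ on signal genes, and a
per-block shared standard-normal latent factor entering as
$b_{ij} = \sqrt{\rho}\, f_{b(i),j}$ — the additive-on-log-scale co-expression
structure the PCA stage is designed to summarize. Signal genes are placed
outside blocks by default (`signal_in_blocks` reverses this), so tests can
separate PCA-stage from lasso-stage behaviour.

Default cohort: 2,000 genes, 100 cases + 100 controls, 20 signal genes at
$\Delta = 1.5$, $\phi = 0.2$, size-factor log-sd 0.25, ten blocks of 20
genes at $\rho = 0.7$, half the cases labelled active. The cohort size
mirrors a typical single-center case-control blood transcriptome study; a
log2 fold change of 1.5 with $\phi = 0.2$ gives per-gene standardized group
separations around 1.3 — strong but within the range of real whole-blood
disease signatures; $\rho = 0.7$ yields within-block correlations near 0.6,
typical of tight co-expression modules.

What the generator deliberately does **not** emulate: an empirical
mean-dispersion trend (one shared $\phi$), batch effects, medication or
other covariates, and gene-length or GC biases. Passing tests therefore
demonstrate correctness of the machinery and recoverability of planted
signal under clean assumptions — not performance on any real cohort.

# Test and verification strategy

The solver is verified against an independent accelerated projected
proximal-gradient solver of the same objective on 200 random small
instances (agreement $10^{-6}$ in objective, $10^{-3}$ per coefficient),
against a box-constrained run of the reference penalized-regression package,
and by KKT certificates on every converged fit. AUC is checked against an
$O(n^2)$ pairwise enumeration; size factors against the worked
median-of-ratios example and the established implementation; PCA against a
dense eigensolver.

Stochastic end-to-end checks run at fixed seeds: the full-scale recovery
experiment uses the default cohort (400 cross-validation fits; median
held-out AUC above 0.9, occurrence-ranking discrimination of planted genes
above 0.8); the permutation null control uses a signal-free 500-gene cohort
with the default composition and 20 label permutations. These problem sizes
keep the whole suite comfortably within a few minutes on one core.

One caveat the null control quantifies: with ten-fold cross-validation on
200 samples a held-out fold has 20 samples, so a single fold's null AUC has
standard deviation about 0.13 and the per-$\lambda$ median of ten folds
about 0.05. Individual medians beyond 0.5 ± 0.15 therefore occur
occasionally by sampling noise alone (3 of 800 in the shipped test), while
the training fits themselves are provably independent of held-out samples
(checked by fit checksums under label flips). Interpret per-$\lambda$
medians on small cohorts with this granularity in mind.

# Known limitations

* The box bounds make the final coefficient magnitudes nearly
  uninformative (many pin at the bound); ranking should rely on occurrence
  counts, which is the point of the stability score.
* Lasso instability among highly correlated transcripts is mitigated, not
  removed, by PCA preselection; interpret single-model gene lists with
  care and prefer genes recurring across contrasts.
* The fold-percentile confidence interval is narrow-sample and
  conservative only in a heuristic sense; a DeLong-type interval on the
  final refit would be an alternative on large folds.
* No GSEA or enrichment step, no multinomial/continuous outcomes, no
  sparse-matrix path (the intended matrices are desk-scale dense).
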