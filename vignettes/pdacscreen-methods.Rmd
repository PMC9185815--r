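---
title: "Faecal metagenomic classification of pancreatic cancer: models, parameters and design choices"
author: "pdacscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Faecal metagenomic classification of pancreatic cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdacscreen)
```

# The problem

Pancreatic ductal adenocarcinoma (PDAC) is usually detected late, and the
only routinely used serum marker, carbohydrate antigen 19-9 (CA19-9), has
limited specificity. Species-level faecal metagenomic profiles carry a
reproducible PDAC signature — a set of enriched species together with a
less specific depletion signature shared with other gut-dysbiotic
conditions — that supports case-control classification. `pdacscreen`
implements that workflow end to end: profile filtering, compositional
normalization with frozen-parameter transfer, repeated cross-validated
LASSO ensembles in two variants, fusion with the coded CA19-9 marker,
specificity-targeted threshold calibration, and cross-disease evaluation on
external cohorts, driven by a synthetic-cohort generator that reproduces
the statistical structure the analysis assumes.

# Normalization: log10, clr, frozen standardization

Model features are relative abundances $x_{ij}$ (feature $j$, sample $i$)
surviving two screens: a prevalence-abundance filter (observed at
$\ge 10^{-5}$ in $\ge 2\%$ of samples, both inclusive; `filterTaxa()`) and
a model-feature screen (maximum abundance $\ge 0.001$;
`filterModelFeatures()`). The normalization is

$$ L_{ij} = \log_{10}(x_{ij} + 10^{-5}), \qquad
   \mathrm{clr}_{ij} = L_{ij} - \frac{1}{p}\sum_{j'} L_{ij'}, \qquad
   z_{ij} = \frac{\mathrm{clr}_{ij} - c_j}{s_j}, $$

with the pseudocount guarding against $\log 0$ (a structural zero maps to
$-5$ before centring), the centred log-ratio step removing per-sample
compositional scale, and $c_j, s_j$ the across-sample mean and sd (with
$n-1$ denominator) of the training clr values. The feature list,
pseudocount, $c_j$ and $s_j$ are frozen in a `NormalizationParams` object;
`applyFrozen()` reapplies them verbatim to any new cohort, imputing model
features missing from the new table as zero abundance (the only choice that
keeps the frozen transform total) and ignoring extra features. Reapplying
the frozen parameters to the training table reproduces the training matrix
bit for bit, which the test suite asserts.

Two numerical edge cases: a feature constant across training samples gets
$s_j = 1$ with a warning (it then contributes a constant, never an error,
on transfer); and the clr centring runs over the features of whatever table
is supplied, so the choice between "model features only" (the default
pipeline behaviour) and a wider feature universe is made by the caller.

# The classifier ensemble

`trainEnsemble()` runs a 10-times-repeated, stratified 10-fold
cross-validation (`makeCvScheme()`). Within each of the 100 training folds,
strictly excluding the held-out fold:

1. the normalization above is fitted on the training samples only;
2. under the `enrichment_constrained` variant (model-2), features with
   training-fold single-feature AUROC $< 0.5$ are removed
   (`enrichmentFilter()`), so the model can only use PDAC-enriched
   directions — the mechanism behind its cross-disease specificity;
3. the L1 cost is selected from a fixed log-spaced grid of 10 values
   ($10^0$ down to $10^{-3}$) by an inner stratified 5-fold loop maximizing
   the AUROC of the pooled inner held-out predictions (ties break to the
   sparser cost);
4. an L1-regularised logistic regression (glmnet) is fitted and the
   held-out fold's probabilities are recorded.

Per-sample cross-validation scores are the arithmetic mean of the held-out
predictions over the 10 repeats; per-feature *robustness* is the fraction
of the 100 fold models with a nonzero coefficient. A full-training-set
normalization is frozen into the ensemble for transfer; external samples
are scored as the mean predicted probability over all 100 fold models,
which is deterministic and invariant to sample order and extra features.

Two properties of this estimator are worth knowing. First, the null
distribution of the cross-validated AUROC (labels carrying no signal) is
centred at 0.5 but wider than for independent scores — test-fold samples
share their fold models, and the AUROC-maximizing inner selection chases
selection noise — with a spread around 0.08–0.09 at $n = 120$. We also
evaluated the `lambda.1se` convention (sparsest cost within one standard
error of the best inner mean AUROC); it made *more* folds degenerate to
constant predictions and thereby widened, not narrowed, the null spread, so
the pooled-maximum rule was kept. Second, a training fold in which *every*
feature is anti-associated cannot generically arise after clr
normalization, because per-sample clr differences sum to zero across
features; the degenerate-fold path (constant predictor 0.5, all-zero
coefficients, ensemble shape preserved) is therefore defensive, and is
exercised directly in the tests.

# CA19-9 fusion and threshold calibration

CA19-9 is coded 1 when the serum level strictly exceeds 37 U/mL and 0
otherwise — including "not available", the clinical coding convention
(`encodeCa199()`). The OR combination adds the code to the mean CV score
(any marker-positive sample outranks every marker-negative one; the range
[0, 2] is left unclipped because ROC evaluation is rank-based); the AND
combination multiplies. `calibrateThreshold()` returns the smallest
observed score value $t$ such that the fraction of training control scores
strictly above $t$ is at most $1 - \text{target specificity}$ (default
0.90, i.e. a 10% false-positive rate among training controls); the
achieved rate can undershoot the target on discrete score sets but never
exceeds it, and raising the target never lowers the threshold. External
cohorts are flagged with the same strict-`>` rule at the frozen threshold
(`evaluateExternal()`), reported per health-status group and pooled over
all non-PDAC samples.

# Diversity and univariate statistics

`hillDiversity()` computes rarefied Hill numbers ($q=0$ richness, $q=1$
exponential Shannon, $q=2$ inverse Simpson; non-increasing in $q$) by
averaging over 100 without-replacement subsamples at a common depth, with
evenness reported as the ratios $q_1/q_0$ and $q_2/q_0$. `brayCurtis()`
wraps the standard Bray-Curtis dissimilarity (optionally on square-root
transformed values); an all-zero sample pair is defined as distance 0 with
a warning. `permanovaTest()` implements the single-factor Gower-centred
partition ($F$ and $R^2$ identical to the one-factor adonis2 model) with
the permutation p-value $(1 + \#\{F^\pi \ge F\})/(1 + n_\pi)$, never below
$1/(n_\pi+1)$; permutations can be restricted within strata (e.g. age/sex
matching groups) and an explicit permutation matrix can be supplied for
exhaustive small-$n$ enumeration. For semi-metric dissimilarities the
between-group sum of squares can come out marginally negative under the
null, so small negative $R^2$ values are admitted, as in adonis2.

`wilcoxonScreen()` tests each feature with a two-sided rank-sum test
(exact enumeration when both groups have at most 10 samples and no ties,
normal approximation with tie correction otherwise; constant features get
$p = 1$), applies Benjamini-Hochberg correction across the tested feature
table, and reports the generalised fold change — the mean over a quantile
grid (0.05 to 0.95 in steps of 0.05, linear-interpolation quantiles) of
the difference in log10 abundance quantiles, reusing the $10^{-5}$
pseudocount — plus the single-feature AUROC (tie-corrected Mann-Whitney).

# The synthetic cohort generator

`syntheticSpec()`/`generateCohort()` emulate the statistical structure the
analysis assumes, not any particular sequencing protocol. Abundance of
species $j$ in sample $i$ is a structural zero with probability
`sparsity`, else $10^{\mu_j + b_j + \sigma_j Z}$, multiplied in cases by
`effectEnriched` ($> 1$) on the enriched marker set or `effectDepleted`
($\in (0,1)$) on the depleted set, then closed to sum 1 per sample. The
defaults — 200 species, $\mu_j \sim U(-4, -2)$, $\sigma_j = 0.7$,
sparsity 0.1, 15 species enriched 4-fold, 12 depleted to 0.25-fold,
60 cases vs 60 controls — describe a *filtered* stool species profile:
species surviving an abundance-prevalence screen are mostly prevalent
(hence the low structural-zero rate, which still exercises the pseudocount
path), and 0.7 log10 units is a typical between-subject spread for
prevalent gut species. Age, sex and sequencing depth are generated
independently of the group by default (the case-control design this
mirrors was age- and sex-matched); an `ageCaseShift` knob reintroduces an
age association for diagnostics. The binary CA19-9 simulator flags cases
with probability 0.80 (sensitivity) and controls with probability 0.25
(one minus specificity), with optional missingness coded to 0.

`generateExternalPanel()` adds, per external cohort, an independent
per-species batch shift $b_j \sim N(0, \texttt{batchLogSd})$ (default 0.2
log10 units, a moderate technical/geographic study effect). "Other
disease" cohorts apply *only* the depleted-set effect — generic dysbiosis
without the PDAC-specific enrichment — "pdac_like" cohorts apply both and
"healthy" neither. All randomness derives from one integer seed via fixed
sub-streams, so every object regenerates bit-identically.

What the generator deliberately does **not** emulate: correlation between
species beyond the closure constraint, phylogenetic structure, depth- or
protocol-dependent zero patterns, missing model features in external
cohorts, or longitudinal sampling. Conclusions drawn from it therefore
validate the *pipeline's statistical behaviour* (signal recovery, null
calibration, leakage-freedom, frozen transfer, specificity mechanism), not
the biology of any real cohort.

## A compositional caveat on the specificity mechanism

Depleting $k$ species by a factor $f$ lowers a sample's mean log10
abundance by $k \log_{10} f / p$, which *raises* the clr value of every
other feature by the same amount (closure itself cancels in the clr). With
the default effect sizes this shift is about $+0.03$ log10 units on each
model feature in a depletion-only cohort. The enrichment-constrained
model-2 carries predominantly positive coefficients, so a purely
depression-driven dysbiosis still nudges its scores upward — its
false-positive rate on such cohorts sits a few points above the trained
10% rather than at or below it, while remaining far below the
unconstrained model-1 (which reacts to the depletion signature directly
through negative coefficients). The constraint buys a large specificity
margin over model-1, not complete immunity; a clr reference restricted to
features outside the model set would decouple the two at the price of a
non-standard normalization, and is deliberately not the default.

# Problem sizes and determinism

The packaged examples and tests run at desk scale by choice: cohorts of
40–120 samples with 30–200 species, ensembles of 10–100 fold models,
PERMANOVA null calibration at 500 replicates of 199 permutations, and
brute-force oracle comparisons at 1000 randomized small instances per
statistic. Every stochastic stage takes an explicit seed, derives fixed
sub-streams from it, and restores the caller's RNG state, so identical
configurations reproduce every numeric output exactly — the pipeline
runner (`runPipeline()`) additionally stamps each artifact with the run
seed and a configuration hash.
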