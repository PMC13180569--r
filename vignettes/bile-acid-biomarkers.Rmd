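---
title: "Bile-acid indices and diagnostic biomarker discovery: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bile-acid indices and diagnostic biomarker discovery: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilemarkers)
```

This vignette is the package's account of its own methods: the models and
procedures it implements, the assumptions behind them, the parameters that
matter, and the places where the design was genuinely open and a choice had
to be made.

## The scientific setting

NMOSD and MS are both inflammatory demyelinating diseases of the central
nervous system, but they demand different treatments, and several MS
therapies can worsen NMOSD. The AQP4-IgG autoantibody settles the diagnosis
when present; in seronegative patients an objective biochemical marker would
be valuable. Serum bile acids are a plausible substrate: they are synthesized
in the liver (primary BAs: cholic and chenodeoxycholic acid and their glycine
and taurine conjugates), transformed by gut microbiota (secondary BAs: the
deoxycholic, lithocholic and ursodeoxycholic families), and act as
immunoregulatory ligands. The package operationalizes the diagnostic
analysis of a 15-analyte targeted BA panel: NMOSD shows elevated primary
conjugates, MS shows a secondary-BA excess, and seronegative NMOSD a marked
secondary-BA deficit, with DCA singled out as the discriminating marker for
seronegative NMOSD versus MS under the decision rule "low DCA indicates
NMOSD".

## The 71-index catalogue

`ba_catalogue()` freezes the derived-index set at 71 entries: 15 raw
concentrations, 17 pools, 31 proportions (each index over TBA, stored as a
fraction in [0, 1]) and 8 ratios. Three design points deserve comment.

* **The "conjugated" pool is narrower than chemistry suggests.** It is
  defined as TCA + TCDCA + GCA + GCDCA — the primary conjugates only —
  because that is the convention of the source analysis this package
  reproduces. The chemically complete partition of TBA into conjugation
  states is available as G-conjugated + T-conjugated + unconjugated, and the
  tests verify that partition exactly.
* **Whether the raw concentrations count toward the 71.** The catalogue
  includes them; with the 17 pools, 31 proportions and 8 ratios this is the
  unique enumeration consistent with both the stated total and every index
  the analysis names. It is frozen in code and exportable as JSON so any
  downstream result can name its exact feature space.
* **Zero denominators produce missing values, never infinities.** A ratio
  with a zero denominator (for example GLCA/TLCA when TLCA is zero) and
  any proportion of an all-zero profile are flagged `NA` and propagated; the
  standardizer and the penalized fits then handle them by neutral-value
  imputation on the z-scale. Infinities would otherwise dominate the
  standardization moments.

Proportions are stored as fractions; rendering as percentages is left to
presentation code.

## The synthetic cohort generator

No patient-level data ship with the package, so `generate_cohort()` is a
first-class, tested module rather than a fixture. Its model:

* **Log-normal concentrations.** For group $g$ and analyte $a$,
  $\log_{10} c \sim N(\mu_a + \delta_{g,a},\ \sigma_a)$. Concentrations are
  positive and right-skewed, and the group contrasts being emulated are
  multiplicative (fold-type enrichment or suppression), which makes the
  log-normal the natural family.
* **Effects in standardized units.** Shifts are configured as
  $\delta = d\,\sigma$. For a two-group comparison on one analyte the
  equal-variance binormal AUC is then the closed form $\Phi(d/\sqrt 2)$,
  which gives the test suite an analytic target: the default MS-versus-
  seronegative-NMOSD gap on log DCA is $d = 2.56$, so the expected DCA AUC is
  $\Phi(1.81) \approx 0.965$.
* **Copula-linked clinical scores.** EDSS (ordinal, half-point steps on
  [0, 10]) and spinal lesion-segment counts are generated from latent
  normals correlated with the analyte z-scores, using the bivariate-normal
  bridge $r = 2\sin(\pi\rho/6)$ from a target Spearman $\rho$ to the latent
  Pearson correlation; the latent score is then pushed through the group's
  marginal (normal for EDSS, Poisson quantile for lesion counts) and
  discretized. Monotone discretization approximately preserves Spearman
  correlation; with the default marginals the realized attenuation is within
  the ±0.05 tolerance the tests enforce at n = 2,000. Correlation targets
  are configured against single analytes (UDCA, DCA, LCA) rather than
  derived pools: pools are sums of several log-normals, so an exact
  pool-level target has no closed-form weight, while the analyte-level
  construction transfers the intended sign and approximate magnitude to the
  pool indices.
* **Feasibility is checked, not patched.** With independent analyte
  z-scores, an EDSS latent requires $\sum_i r_i^2 \le 1$; a configuration
  violating this is rejected with the offending group named, because it has
  no positive-semidefinite latent covariance.
* **Defaults are directionally calibrated.** Group sizes (80/32/50/66) match
  the emulated study design. Baseline log-means follow a plausible
  physiologic ordering (glyco-conjugates above tauro-conjugates above
  unconjugated secondaries, GCDCA the most abundant analyte) and log-SDs of
  0.35–0.40; the emulated study reports group medians only in supplementary
  material not available here, so the defaults are claims about realism, not
  about that study's values. EDSS marginals anchor the NMOSD median near 4
  and MS near 3; healthy controls carry no EDSS.

What the generator does **not** emulate — and therefore what passing tests do
not establish about real data: inter-analyte correlation (real BA panels are
strongly positively correlated because they share synthesis and clearance
pathways; here analytes are independent within group, which makes the
selection problem *easier* than in practice), lower-limit-of-quantification
censoring, batch and instrument drift, medication effects, and any
longitudinal structure. Results on synthetic cohorts validate the machinery,
not the clinical claim.

## Leakage-safe preprocessing

* **Split arithmetic.** `stratified_split()` allocates the test set by
  largest remainder with total $\lceil f \cdot n \rceil$: per-stratum quotas
  $f \cdot n_s$ are floored and the remaining seats go to the largest
  fractional remainders. This is the convention under which a 112 + 50
  cohort at $f = 0.2$ yields 129 train / 33 test (23 + 10), each stratum
  within one subject of its exact quota. A rounded total would give 32 and
  break that arithmetic.
* **Standardization.** Z-scoring uses training-set moments only (sample SD,
  denominator $n-1$); the fitted parameters are applied verbatim to
  validation and test rows. Zero-variance training columns are dropped with
  a warning — they carry no signal and destabilize penalized fits if given
  an artificial scale.

## Stability selection

The selection engine is a nested cross-validation: an outer stratified
5-fold loop for honest frequency estimation, and within each outer training
portion an inner stratified 5-fold cross-validated L1-penalized logistic
regression. Numerical conventions: binomial deviance as the CV loss (the
natural loss for penalized logistic regression), a 100-point log-spaced
penalty grid from the data-derived $\lambda_{\max}$ down to
$10^{-3}\lambda_{\max}$, an unpenalized intercept, and no internal rescaling
(features arrive standardized). The penalty is chosen by the
one-standard-error rule: the largest $\lambda$ whose mean CV error is within
one standard error (SD across folds / $\sqrt k$) of the minimum —
`lambda_1se_rule()` implements the rule on any error curve and is
cross-checked in the tests against the reference implementation in glmnet,
which performs the penalized fits themselves.

A feature's stability score is the fraction of the 5 outer folds in which it
is active at $\lambda_{1se}$, so scores are multiples of 20%; the retained
set is scores ≥ 50%. The fold-frequency definition is deliberate: this is
*not* the randomized-subsampling variant of stability selection, and no
per-family error bound is claimed for the 50% threshold. A single-run
10-fold cross-validated LASSO on the whole training set
(`single_lasso_reference()`) provides the conventional comparator; the
10-fold choice for the reference (versus 5 inside the nesting) mirrors the
two roles the procedure plays — the nested loop estimates selection
stability, the single run produces the comparison model.

## The classifier benchmark

Five models: logistic regression on the stable features, random forest,
linear-kernel SVM, gradient-boosted trees, and LASSO+logistic. The
hyperparameter grids are frozen in `default_grid()` and searched by mean AUC
over stratified inner folds; grids are deliberately small (the training sets
are ~130 subjects). SVM probabilities come from the Platt-type sigmoid
calibration fit during training. The positive class is NMOSD throughout —
identifying NMOSD is the clinical priority.

Validation has three pre-specified levels: (1) 10 repetitions of stratified
5-fold cross-validation on the training set, retraining each model with its
selected hyperparameters, summarized as mean ± SD and coefficient of
variation over the 50 fold AUCs; (2) 1,000 stratified bootstrap resamples of
the test set, giving a percentile AUC interval per model; (3) the hold-out
metric panel. The panel is reported at **two** thresholds — the
Youden-optimal one and the conventional 0.5 — because accuracy and
sensitivity/specificity columns of a small hold-out set cannot in general be
reconciled under a single threshold; reporting both removes the ambiguity.
Metric identities (balanced accuracy = (sens + spec)/2,
J = sens + spec − 1, F1 = 2TP/(2TP + FP + FN)) are exact by construction and
property-tested against a brute-force confusion-matrix oracle.

Model comparison uses the Friedman rank test over the models × 50-fold AUC
matrix — the only model-by-block matrix the pipeline produces at matched
granularity — followed, when significant, by paired t-tests on the matched
test-set bootstrap AUC samples with Holm step-down adjustment. Clinical
utility is assessed by decision curves (net benefit
$TP/n - (FP/n)\,p_t/(1-p_t)$ over $p_t \in \{0.01, \dots, 0.99\}$) and by
category-free NRI and IDI against the stable-features logistic baseline; the
continuous NRI variant is used because no clinical risk categories exist for
this decision.

## Single-marker inference

The marker suite treats orientation as an *input*: for DCA the rule "low
values indicate seronegative NMOSD" is fixed a priori, and the AUC is never
auto-flipped — an auto-oriented AUC is biased upward. Conventions:

* AUC is the Mann–Whitney pair statistic computed by mid-ranks.
* The DeLong variance comes from the placement-value covariance estimator;
  the Wald interval is truncated to [0, 1], and perfect separation yields a
  zero-width interval at 1 (constant placement values) rather than an error.
* Youden cutoffs are reported as midpoints between adjacent distinct
  observed values, in original marker units, with ties in J broken toward
  higher specificity (favoring fewer false positives); an all-tied marker
  returns J = 0 at the single observed value.
* The bootstrap interval is the 2.5/97.5 percentile of stratified resamples
  (percentile rather than BCa, matching how such intervals are conventionally
  reported for AUCs).
* The permutation p uses the add-one correction
  $(1 + \#\{AUC^\pi \ge AUC\})/(B+1)$: it is never zero, and its floor at
  $B = 5000$ is $1/5001 \approx 2\times10^{-4}$.
* Repeated holdout (1,000 stratified 20/80 splits) and repeated stratified
  5-fold CV (200 repetitions, recording each repetition's fold-mean AUC)
  probe sampling stability; the fold-mean averaging makes the k-fold
  interval systematically narrower than the holdout range.

## Cohort-level statistics

Group comparisons use the Kruskal–Wallis H test (tie-corrected mid-ranks,
chi-squared reference); across the 71 indices a Benjamini–Hochberg FDR is
reported alongside the raw p-values — raw p remains primary for fidelity to
conventional reporting, the FDR column is there because a reusable tool
should expose it. Spearman correlations use the asymptotic t approximation
and drop missing pairs. PCA is computed on standardized indices
(correlation-scale), since the indices span orders of magnitude in units.
Categorical comparisons use plain Pearson chi-squared without continuity
correction.

## Problem sizes and numerical tolerances

The test suite exercises the machinery at the scale of the emulated study
(cohorts of 228, training sets of 129) and verifies stochastic behaviour by
Monte Carlo at sizes chosen for tight-but-honest checks: catalogue-oracle
equivalence on 1,000 random profiles at $10^{-12}$ relative tolerance, pool
partitions at $10^{-9}$, DeLong coverage over 2,000 replicates and bootstrap
coverage over 500 replicates (B = 500) at a ±2% band around the nominal
95%, permutation-null calibration over 500 runs, planted-effect recovery of
stability selection over 50 seeds (recall ≥ 0.9, false retention ≤ 0.1), and
the planted-DCA binormal check over 200 generated cohorts within ±0.03 of
$\Phi(2.56/\sqrt2)$. Exact identities (metric arithmetic, treat-all net
benefit, Holm ordering) are asserted to machine precision.

## Known limitations

* Synthetic analytes are independent within group; real panels are
  correlated, so real-data stability scores will be more diffuse than the
  synthetic ones.
* The 50% stability threshold and the frozen hyperparameter grids are
  conventions of the emulated analysis, not tuned quantities; no optimality
  is claimed.
* NRI/IDI are reported without analytic standard errors (bootstrap
  percentile only), and the decision-curve module draws no threshold-range
  recommendation.
* The pipeline validates internally (nested CV, bootstrap, hold-out); it
  cannot substitute for external multi-center validation of any clinical
  cutoff, and the synthetic DCA cutoff value itself is meaningless outside
  the generator's concentration scale.
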