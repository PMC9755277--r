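---
title: "Measuring and decomposing socio-economic inequality in minimum dietary diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing socio-economic inequality in minimum dietary diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddineq)
```

## The measurement problem

Minimum dietary diversity (MDD) is the binary infant-and-young-child-feeding
indicator: a child aged 6–23 months met MDD if, on the previous day, it
consumed foods from at least 5 of 8 defined groups (breastfeeding; grains,
roots and tubers; legumes and nuts; dairy; flesh foods; eggs; vitamin-A-rich
fruits and vegetables; other fruits and vegetables). National surveys such as
the Bangladesh Demographic and Health Survey (BDHS) show that meeting MDD is
not evenly spread across living standards: children of wealthier and more
educated mothers meet it more often. This package provides the standard
machinery for quantifying that inequality from a child-recode-style survey
table — with sampling weights and a stratified-cluster design — and for
attributing it to covariates.

## The concentration index and its estimation

Rank children from poorest to richest by a living-standards variable (the
asset-based wealth quintile, or maternal education). With weights normalised
to sum to one, each tie group of the ranking variable receives the shared
**fractional rank** `r = F(lower groups) + f(own group)/2`, the midpoint of
its interval in the weighted cumulative distribution. This is the standard
correction for grouped rankings; it makes the weighted mean rank exactly 0.5.

The **concentration curve** plots the cumulative weighted share of children
meeting MDD against the cumulative weighted population share in rank order.
The **concentration index** is computed by the convenient covariance
approach,

CIX = (2 / mu) * cov_w(h, r),

where `h` is the MDD indicator and `mu` its weighted mean. The weighted
covariance uses the population convention (no n−1 correction); under that
convention the formula is exact, twice the signed area between the equality
diagonal and the curve reproduces the index *exactly* on grouped data (the
test suite asserts this at 1e−12, not merely within piecewise-linear error),
and the index obeys `CIX ∈ [mu − 1, 1 − mu]` for a binary outcome. Positive
values mean MDD is concentrated among the better-off.

### Inference

`concentration_index()` reports a standard error through the convenient
regression: the weighted least-squares slope of `2 var_w(r) h / mu` on `r`
equals the index, so its robust variance is the index's variance. We use
HC1 heteroskedasticity-robust errors, or cluster-robust errors by the
primary sampling unit when a cluster column is supplied — standard practice
for DHS-style data, whose observations are correlated within enumeration
areas. P-values use a t reference with `clusters − 1` degrees of freedom
(or `n − 2` unclustered). Under a null data-generating process the test's
empirical size at `alpha = 0.05`, measured over 500 simulated surveys of
1,000 children with 100 clusters, sits near the nominal level (the
acceptance script recomputes it on every run; it is typically 0.04–0.06 and
mildly conservative, as expected for t-based cluster-robust inference).

### Design decisions worth knowing

* **Ranking by quintile, not by continuous score.** Surveys distribute the
  wealth index both as a continuous score and as quintiles. We default to
  ranking by the quintile (with tie-midpoint ranks) because the
  decomposition treats wealth categorically and the published row structure
  is then internally reproducible; ranking by the continuous score is
  available by passing the score column instead. The choice matters for the
  residual term (below).
* **Closed age interval [6, 23] months.** Both boundary ages are retained,
  matching how "children aged 6–23 months" is used in survey reporting.
* **No binary-outcome normalisation.** The plain index is reported, not the
  Wagstaff or Erreygers normalisation; for a binary outcome the attainable
  range shrinks to `[mu − 1, 1 − mu]`, which the estimates respect by
  construction. A normalised variant was deliberately left out of scope to
  keep reported values comparable with conventional published tables.
* **Significance threshold** for the component labels is 0.05.

## Decomposition into covariate contributions

Fit the weighted linear probability model (LPM)

y = alpha + sum_k beta_k X_k + eps

on treatment-coded dummies of the covariates (mother's age group and
education, wealth quintile, partner education, residence, media exposure,
work status, post-natal visit, ANC visit category, child sex, parity
category, division — reference categories: first level of each, e.g.
poorest, no education, Barisal). Because OLS residuals satisfy the linear
identity exactly, the index decomposes exactly:

CIX = sum_k (beta_k Xbar_k / mu) C_k + GC_eps / mu,

where `C_k = (2 / Xbar_k) cov_w(X_k, r)` is the concentration index of
dummy `k` over the *same* ranks as the overall index, `beta_k Xbar_k / mu`
is the elasticity, and `GC_eps = 2 cov_w(eps, r)` is the generalized
concentration index of the residuals. `decompose_cix()` computes the
residual both directly from `eps` and as `overall − explained` and refuses
to return if the two disagree beyond 1e−8; the identity
`explained + residual = overall` therefore holds to numerical precision on
every dataset the package processes.

Two consequences of these conventions deserve emphasis:

* **A structurally zero residual.** When the ranking variable is the
  quintile and its dummies are in the regression, the rank vector is
  constant within quintiles and hence lies in the span of the intercept and
  the wealth dummies; the OLS residuals are orthogonal to that span, so
  `GC_eps = 0` *identically* and the explained share is exactly 100%. A
  nonzero residual arises only when the ranks carry within-category
  variation (continuous-score ranking) or the regression omits the ranking
  variable's categories. Published tables with small nonzero residuals are
  therefore most consistent with continuous-score ranking.
* **LPM, not probit/logit.** The decomposition identity is exact only for a
  linear model; marginal-effect approximations trade exactness for link
  realism. We implement the linear model only.

The percentage contribution of each row is `contribution / CIX * 100`;
negative percentages mark factors that *reduce* the observed concentration.
Report output rounds elasticities, component indices and contributions to 4
decimals and percentages to 2, the conventional table precision.

## Verifying published tables

`verify_published_table()` re-derives, from a transcription of a published
decomposition table (printed numbers kept as strings so their precision is
known), every arithmetic relation the table asserts: per-row
`contribution = elasticity × C_k` and `pct = contribution / overall × 100`,
per-variable totals, and the explained/residual split. Each comparison
carries a tolerance that propagates half an ulp of every printed input
through the recomputation, so a flag means the printed numbers cannot be
reconciled *at their own precision* — a finding about the table, not an
estimation discrepancy. On the bundled transcriptions of the BDHS 2017–18
MDD decomposition tables, 138 of 144 checks reconcile; the verifier flags
the wealth-ranked table's absolute residual (printed 0.00528 where
overall − explained = 0.00258, even though the printed percentage split
97.92 + 2.08 = 100 is coherent), one mother's-age row of the
education-ranked table (printed contribution 0.0031 where the printed
elasticity × C_k cannot exceed 0.0030), and that table's education total
(printed rows sum to 0.0707, printed total 0.0715).

## The synthetic survey generator

Because DHS microdata are distributed under access agreements, the package
validates itself on a synthetic child-recode generator
(`generate_survey()`) whose inequality structure is known exactly.

* **Outcome model.** Each of the 8 food-group flags is an independent
  Bernoulli draw with probability
  `clip(base_g + wealth_offset[q, g] + education_offset[e, g], 0, 1)` —
  additive SES gradients on the probability scale. The defaults raise
  dairy, eggs, flesh foods and both fruit-vegetable groups with wealth and
  education and lower breastfeeding (the familiar reverse gradient), with
  baseline probabilities chosen to resemble Bangladeshi IYCF marginals.
* **Prevalence calibration.** A single additive shift on the logit of the
  baseline probabilities is solved by bisection so that the analytic
  weighted prevalence among 6–23-month-olds equals the configured target,
  37.47% by default — the regime reported for BDHS 2017–18. The analytic
  prevalence is an exact Poisson-binomial tail summed over the finite
  (quintile × education × age band) grid, and the generated cohorts
  converge to it (tested at n = 100,000 within 3 standard errors).
* **Design features.** Weights are log-normal with configurable CV
  (default 0.5, resembling the dispersion of DHS design weights) rescaled
  to mean 1; wealth quintiles are exact weighted fifths of a latent
  household score, so each quintile's weighted share is 0.20 up to one
  observation's weight; maternal education is drawn conditionally on the
  quintile from a configurable 5 × 4 table (default mildly positive
  association, with an independent option for tests); 16 strata are
  realised as division × residence with clusters of ~30 children nested in
  them; about 9% of households contribute two children; ten asset
  indicators load on the latent wealth score so the PCA wealth index can be
  rebuilt and compared against the design quintiles.
* **Missingness** is MCAR at a per-field default of 2% on the food-group
  flags and a subset of covariate fields — sufficient to exercise the
  filter cascade, which deletes incomplete responses exactly as the
  analysis protocol prescribes. MCAR keeps complete-case prevalence
  unbiased; the generator does not emulate informative missingness.
* **What it does not emulate.** No probability-proportional-to-size
  two-stage sampling machinery, no cluster-level random effects in the
  outcome, no informative weighting, and the non-SES covariates (ANC,
  media, post-natal care) are *correlated with* wealth and education but do
  not causally affect the outcome. Passing tests therefore demonstrate
  correctness of the estimators under a clean additive data-generating
  process, not robustness to design effects absent from the generator.

### The analytic oracle

`true_decomposition()` computes, by brute-force expectation over the finite
covariate grid, the asymptotic limit of the sample decomposition under a
clipping-free configuration: cell-level MDD probabilities (exact
Poisson-binomial tails) are projected by weighted least squares onto the
wealth + education dummy design, giving the elasticities, component
indices and contribution shares the sample pipeline must recover.
Configurations whose cell probabilities leave [0, 1] are refused (class
`mddineq_clipping_error`) because clipping breaks additivity. Parameter
recovery is tested at n = 200,000 with a mixed-gradient configuration: the
estimated per-variable contribution shares must match the oracle within 3
Monte-Carlo standard errors (25-replicate nonparametric bootstrap); in
practice they agree within a fraction of one standard error.

## Numerical conventions and degenerate inputs

* Weighted covariance: normalised weights, population convention, used
  consistently in ranks, index, curve, and decomposition.
* Quantile boundaries: a tie-group midpoint exactly on a quintile boundary
  goes to the *lower* quintile; ties always share a quintile.
* PCA sign: the first principal axis is anchored to correlate positively
  with a declared affluence indicator; constant asset columns are dropped
  with a warning; fewer than five distinct scores is an error.
* `mu = 0` (outcome never occurs) makes the index undefined and is an
  error; subgroups and food-group components in that state are flagged and
  excluded from comparisons rather than silently zeroed.
* A single-observation subgroup has covariance zero with its own rank
  (0.5), hence index 0 with an undefined standard error.
* Collinear dummy designs are refused with the aliased columns named.

## Problem sizes used in the validation suite

The test suite draws cohorts of 400–8,000 children for behavioural tests,
40,000 for subgroup-structure recovery, 100,000 for the prevalence
invariant, and 200,000 for decomposition parameter recovery; the null-size
simulation uses 500 replicates of 1,000 children. These sizes were chosen
so that Monte-Carlo error is small relative to the tolerances being
asserted while the whole suite stays fast.

## Known limitations

* The decomposition is descriptive, not causal: contributions quantify the
  covariance structure of the linear projection, and omitting a generating
  covariate reallocates its contribution to correlated covariates and the
  residual (the identity still holds).
* The convenient-regression standard error ignores the uncertainty in
  estimated ranks and in `mu`; this is the standard practice it mirrors.
* The wealth index is a single national PCA; the urban/rural split-sample
  composite refinement used in some DHS rounds is not implemented.
* Curve dominance is reported as a flag (every interior point on one side
  of the diagonal, at least one strictly), not as a formal dominance test.
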