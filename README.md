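# mddineq

Survey-weighted measurement and decomposition of socio-economic inequality
in **minimum dietary diversity (MDD)** — the binary IYCF indicator that a
child aged 6–23 months consumed at least 5 of 8 food groups the previous
day — from DHS-style child-recode tables.

The package is aimed at health-inequality analysts working with
(B)DHS-like microdata: it implements the full pipeline used in published
concentration-index analyses of child nutrition, plus a calibrated
synthetic survey generator so every stage is testable without restricted
microdata.

## What it computes

With weights normalised to sum 1 and `r` the weighted fractional rank of
children over a living-standards variable (wealth quintile or maternal
education; tie groups share midpoint ranks), the concentration index of
the MDD indicator `h` is computed by the convenient covariance approach

```
CIX = (2 / mu) * cov_w(h, r),        mu = weighted mean of h,
```

with HC1 or cluster-robust standard errors via the convenient-regression
equivalence. The index is decomposed through the weighted linear
probability model `y = alpha + sum_k beta_k X_k + eps` as

```
CIX = sum_k (beta_k * Xbar_k / mu) * C_k  +  GC_eps / mu,
```

where `C_k = (2 / Xbar_k) cov_w(X_k, r)` uses the same ranks as the overall
index and `GC_eps / mu` is the unexplained residual; the identity
`explained + residual = overall` holds to numerical precision by
construction. Supporting stages: covariate recodes (media exposure, ANC
category, parity, age bands), the three-stage cohort filter cascade,
weighted descriptives, concentration curves with dominance flags,
subgroup and per-food-group index sweeps, an asset-based wealth index by
weighted PCA cut into weighted quintiles, and an arithmetic verifier for
published decomposition tables.

## Worked example

The numbered drivers under `analysis/` run the whole study on a synthetic
cohort (`Rscript analysis/01_simulate.R` … `06_verify_published.R`),
writing tables and figures under `results/analysis/`. The same thing in a
few lines:

```r
library(mddineq)

cfg    <- generator_config(seed = 20178)       # ~6,000 children, MDD target 37.47%
survey <- recode_covariates(generate_survey(cfg))
cohort <- apply_filter_cascade(survey)$table   # age 6-23, complete responses
cohort$mdd <- compute_mdd(cohort)$mdd

ranks <- weighted_fractional_rank(cohort$wealth_quintile, cohort$weight,
                                  variable = "wealth_quintile")
cix <- concentration_index(cohort$mdd, ranks, cohort$weight,
                           cluster = cohort$cluster_id)
print(cix)
#> Concentration index (ranked by wealth_quintile): 0.1513 (se 0.0167, p 1.05e-16; mu = 0.3716, n = 2307)

dec <- decompose_cix(fit_lpm(cohort, "mdd"), ranks, cohort$weight, cix)
```

On this cohort the weighted MDD prevalence is 37.16% (the generator's
analytic value is 37.47%), MDD is significantly concentrated among the
better-off (`CIX = 0.1513`, p < 0.001 ranked by wealth; `0.1105` ranked by
maternal education), the concentration curves lie below the line of
equality, and the decomposition attributes 83.4% of the wealth-ranked
index to wealth quintile and 16.6% to maternal education — as expected,
since the generator injects inequality only through those two variables.
With quintile-based ranks and wealth dummies in the regression the
residual term is structurally zero (see the methods vignette,
`vignettes/mdd-inequality-methods.Rmd`).

Interpretation of the columns: `elasticity` is `beta_k * Xbar_k / mu`,
`c_k` the component concentration index of the dummy over the same ranks,
`contribution` their product, and `pct_contribution` its share of the
overall index (negative = the factor pulls concentration down).

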