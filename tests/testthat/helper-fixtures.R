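# Shared fixtures: all data is generated in code at test time.

# A small, clean configuration (no missingness, no prevalence calibration)
# for tests that need a complete cohort quickly.
tiny_config <- function(n = 800, seed = 101, ...) {
  generator_config(n_children = n, seed = seed, missing_rate = 0,
                   target_prevalence = NULL, ...)
}

# Clipping-free mixed-gradient configuration used for oracle comparisons.
recovery_config <- function(n = 200000, seed = 11) {
  generator_config(
    n_children = n, seed = seed,
    base_group_probs = c(0.5, 0.55, 0.35, 0.4, 0.45, 0.35, 0.5, 0.4),
    wealth_gradient = c(-0.08, -0.04, 0, 0.04, 0.08),
    education_gradient = c(-0.06, -0.02, 0.02, 0.06),
    target_prevalence = NULL, missing_rate = 0)
}

# Generate, recode and filter in one step; appends the MDD outcome.
make_cohort <- function(cfg, covariates = mdd_model_covariates()) {
  tab <- recode_covariates(generate_survey(cfg))
  cc <- apply_filter_cascade(tab, covariates = covariates)
  coh <- cc$table
  out <- compute_mdd(coh)
  coh$mdd <- out$mdd
  coh$n_food_groups <- out$n_groups
  coh
}

# Hand-built five-child table exercising the cascade stages.
toy_survey <- function(ages = c(4L, 6L, 23L, 24L, 30L)) {
  n <- length(ages)
  fg <- matrix(1L, n, 8, dimnames = list(NULL, food_group_columns()))
  data.frame(
    child_id = sprintf("c%02d", seq_len(n)),
    weight = rep(1, n),
    cluster_id = "c1", stratum_id = "s1",
    child_age_months = ages,
    fg,
    wealth_quintile = factor("middle", c("poorest", "poorer", "middle", "richer", "richest"), ordered = TRUE),
    mother_education = factor("primary", c("none", "primary", "secondary", "higher"), ordered = TRUE),
    check.names = FALSE
  )
}

# Per-variable contribution shares of the wealth-ranked decomposition on a
# wealth + education design; the quantity the generator oracle predicts.
decomposition_shares <- function(coh) {
  fr <- weighted_fractional_rank(coh$wealth_quintile, coh$weight,
                                 variable = "wealth_quintile")
  ci <- concentration_index(coh$mdd, fr, coh$weight)
  fit <- fit_lpm(coh, "mdd", covariates = c("wealth_quintile", "mother_education"))
  dec <- decompose_cix(fit, fr, coh$weight, ci)
  tapply(dec$rows$contribution, dec$rows$variable, sum) / ci$value
}

# Independent brute-force expansion of the convenient covariance formula:
# CIX = (2/mu) * (sum_i wn_i h_i r_i - mu * rbar).
cix_bruteforce <- function(h, r, w) {
  wn <- w / sum(w)
  mu <- sum(wn * h)
  (2 / mu) * (sum(wn * h * r) - mu * sum(wn * r))
}
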