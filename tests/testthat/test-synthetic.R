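test_that("generator configs are validated with the offending field named", {
  expect_error(generator_config(n_children = 0), "n_children")
  expect_error(generator_config(n_children = 10.5), "n_children")
  expect_error(generator_config(base_group_probs = rep(0.5, 7)), "base_group_probs")
  expect_error(generator_config(base_group_probs = c(rep(0.5, 7), 1.2)), "base_group_probs")
  expect_error(generator_config(weight_dispersion = -0.1), "weight_dispersion")
  expect_error(generator_config(missing_rate = 1), "missing_rate")
  expect_error(generator_config(target_prevalence = 0), "target_prevalence")
  expect_error(generator_config(wealth_gradient = rep(0, 4)), "wealth_gradient")
  expect_error(generator_config(education_by_wealth = matrix(1, 5, 4)),
               "education_by_wealth")
})

test_that("the same seed reproduces the survey table exactly", {
  cfg <- generator_config(n_children = 400, seed = 77)
  expect_identical(generate_survey(cfg), generate_survey(cfg))
  cfg2 <- generator_config(n_children = 400, seed = 78)
  expect_false(identical(generate_survey(cfg)$weight, generate_survey(cfg2)$weight))
})

test_that("null-gradient prevalence matches the closed-form binomial tail", {
  # with p = 0.5 for every group, P(count >= 5) = P(Binomial(8, 0.5) >= 5)
  p_exact <- sum(dbinom(5:8, 8, 0.5))
  expect_equal(p_exact, 0.36328125)

  cfg <- generator_config(n_children = 2000, seed = 3,
                          base_group_probs = rep(0.5, 8),
                          wealth_gradient = rep(0, 5),
                          education_gradient = rep(0, 4),
                          target_prevalence = NULL, missing_rate = 0)
  expect_equal(analytic_mdd_prevalence(cfg), p_exact, tolerance = 1e-12)

  coh <- make_cohort(cfg, covariates = c("wealth_quintile", "mother_education"))
  wn <- coh$weight / sum(coh$weight)
  prev <- sum(wn * coh$mdd)
  se <- sqrt(sum(wn^2) * p_exact * (1 - p_exact))
  expect_lt(abs(prev - p_exact), 3 * se)
})

test_that("weights are positive with mean one and the requested dispersion", {
  tab <- generate_survey(generator_config(n_children = 5000, seed = 2,
                                          weight_dispersion = 0.5))
  expect_true(all(tab$weight > 0))
  expect_equal(mean(tab$weight), 1, tolerance = 1e-12)
  expect_equal(sd(tab$weight) / mean(tab$weight), 0.5, tolerance = 0.05)
  tab0 <- generate_survey(generator_config(n_children = 100, seed = 2,
                                           weight_dispersion = 0))
  expect_true(all(tab0$weight == 1))
})

test_that("wealth quintiles are exact weighted fifths up to one observation's weight", {
  tab <- generate_survey(generator_config(n_children = 3000, seed = 5))
  wn <- tab$weight / sum(tab$weight)
  shares <- tapply(wn, tab$wealth_quintile, sum)
  expect_equal(length(shares), 5L)
  expect_true(all(abs(shares - 0.2) <= max(wn) + 1e-12))
})

test_that("weighted MDD prevalence converges to the analytic grid value", {
  cfg <- generator_config(n_children = 100000, seed = 13)
  prev_true <- analytic_mdd_prevalence(cfg)
  expect_equal(prev_true, 0.3747, tolerance = 1e-9) # calibrated target
  coh <- make_cohort(cfg)
  wn <- coh$weight / sum(coh$weight)
  prev <- sum(wn * coh$mdd)
  se <- sqrt(sum(wn^2) * prev_true * (1 - prev_true))
  expect_lt(abs(prev - prev_true), 3 * se)
})

test_that("the analytic decomposition oracle reflects the injected structure", {
  # no gradients: every contribution is zero and so is the index
  null_cfg <- tiny_config(wealth_gradient = rep(0, 5), education_gradient = rep(0, 4))
  td0 <- true_decomposition(null_cfg)
  expect_equal(max(abs(td0$rows$contribution)), 0, tolerance = 1e-14)
  expect_equal(td0$cix, 0, tolerance = 1e-14)

  # wealth-only gradient with education independent of wealth:
  # education picks up no contribution
  indep <- matrix(rep(c(0.07, 0.27, 0.48, 0.18), each = 5), 5, 4)
  td1 <- true_decomposition(tiny_config(
    wealth_gradient = c(-0.05, -0.025, 0, 0.025, 0.05),
    education_gradient = rep(0, 4),
    education_by_wealth = indep))
  expect_equal(unname(td1$variable_shares["mother_education"]), 0, tolerance = 1e-10)
  expect_gt(td1$cix, 0)

  # configurations where clipping distorts additivity are refused
  clip_cfg <- tiny_config(base_group_probs = rep(0.9, 8),
                          wealth_gradient = c(-0.3, -0.15, 0, 0.15, 0.3))
  expect_error(true_decomposition(clip_cfg), class = "mddineq_clipping_error")
})

test_that("a positive wealth gradient produces a significantly positive wealth CIX", {
  cfg <- tiny_config(n = 8000, seed = 19,
                     wealth_gradient = c(-0.08, -0.04, 0, 0.04, 0.08))
  coh <- make_cohort(cfg)
  fr <- weighted_fractional_rank(coh$wealth_quintile, coh$weight,
                                 variable = "wealth_quintile")
  ci <- concentration_index(coh$mdd, fr, coh$weight, cluster = coh$cluster_id)
  expect_gt(ci$value, 0)
  expect_lt(ci$p_value, 0.001)
})

test_that("survey tables round-trip through CSV with schema intact", {
  cfg <- generator_config(n_children = 300, seed = 8)
  tab <- generate_survey(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(tab, path)
  expect_true(file.exists(paste0(path, ".config.yaml")))
  back <- read_survey_csv(path)
  expect_identical(nrow(back), nrow(tab))
  expect_identical(levels(back$wealth_quintile), levels(tab$wealth_quintile))
  expect_true(is.ordered(back$mother_education))
  expect_equal(back$weight, tab$weight, tolerance = 1e-12)
  expect_identical(back$fg_dairy, tab$fg_dairy)
})
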