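test_that("a perfectly explained outcome decomposes without residual", {
  # y equals one dummy exactly: beta = 1, alpha = 0, zero residuals,
  # and the dummy's contribution is the whole index
  n <- 40
  tab <- data.frame(
    x = factor(rep(c("lo", "hi"), each = n / 2), levels = c("lo", "hi")),
    weight = rexp(n) + 0.5)
  tab$y <- as.numeric(tab$x == "hi")
  fit <- fit_lpm(tab, "y", covariates = "x", references = list(x = "lo"))
  expect_equal(unname(fit$beta), 1, tolerance = 1e-12)
  expect_equal(fit$alpha, 0, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)

  fr <- weighted_fractional_rank(as.integer(tab$x), tab$weight, variable = "x")
  overall <- concentration_index(tab$y, fr, tab$weight)
  dec <- decompose_cix(fit, fr, tab$weight, overall)
  expect_equal(dec$rows$contribution, overall$value, tolerance = 1e-12)
  expect_equal(dec$residual, 0, tolerance = 1e-12)
  expect_equal(dec$rows$pct_contribution, 100, tolerance = 1e-9)
})

test_that("LPM coefficients equal weighted subgroup mean differences (group-means oracle)", {
  set.seed(71)
  n <- 300
  g <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  w <- rexp(n) + 0.2
  y <- rbinom(n, 1, c(a = 0.2, b = 0.5, c = 0.7)[as.character(g)])
  tab <- data.frame(g = g, weight = w, y = y)
  fit <- fit_lpm(tab, "y", covariates = "g", references = list(g = "a"))

  gm <- vapply(levels(g), function(l) weighted.mean(y[g == l], w[g == l]), numeric(1))
  expect_equal(unname(fit$alpha), unname(gm["a"]), tolerance = 1e-10)
  expect_equal(unname(fit$beta[["gb"]]), unname(gm["b"] - gm["a"]), tolerance = 1e-10)
  expect_equal(unname(fit$beta[["gc"]]), unname(gm["c"] - gm["a"]), tolerance = 1e-10)
  # weighted dummy means
  expect_equal(unname(fit$xbar[["gb"]]), sum(w[g == "b"]) / sum(w), tolerance = 1e-12)
})

test_that("collinear designs are refused with the aliased dummies named", {
  n <- 60
  tab <- data.frame(
    x = factor(rep(c("lo", "hi"), each = n / 2)),
    weight = 1, y = rbinom(n, 1, 0.5))
  tab$dup <- tab$x # identical factor: its dummy is aliased
  expect_error(fit_lpm(tab, "y", covariates = c("x", "dup")), "aliased.*dup")
  expect_error(fit_lpm(tab, "y", covariates = c("x", "missing_col")), "missing_col")
  tab$const <- factor("only")
  expect_error(fit_lpm(tab, "y", covariates = c("x", "const")), "single observed category")
})

test_that("explained + residual reproduces the overall index on generated cohorts", {
  for (seed in c(81, 82)) {
    coh <- make_cohort(tiny_config(n = 1200, seed = seed))
    fr <- weighted_fractional_rank(coh$wealth_quintile, coh$weight,
                                   variable = "wealth_quintile")
    overall <- concentration_index(coh$mdd, fr, coh$weight)
    fit <- fit_lpm(coh, "mdd")
    dec <- decompose_cix(fit, fr, coh$weight, overall)
    expect_lt(abs(dec$explained + dec$residual - overall$value), 1e-10)
    expect_lt(abs(dec$pct_explained + dec$pct_residual - 100), 1e-8)
    # per-row identity: contribution = elasticity x C_k
    expect_lt(max(abs(dec$rows$contribution - dec$rows$elasticity * dec$rows$c_k)), 1e-12)
    # variable totals sum the rows
    for (v in dec$variable_totals$variable) {
      expect_equal(dec$variable_totals$contribution[dec$variable_totals$variable == v],
                   sum(dec$rows$contribution[dec$rows$variable == v]), tolerance = 1e-12)
    }
    # mismatched ranks are caught by the internal-consistency guard
    wrong <- weighted_fractional_rank(rev(as.integer(coh$wealth_quintile)), coh$weight)
    expect_error(decompose_cix(fit, wrong, coh$weight, overall), "internal inconsistency")
  }
})

test_that("published worked examples reproduce at printed precision", {
  # richest-quintile row of the wealth-ranked table
  expect_equal(round(0.0731 * 0.8079, 4), 0.0591)
  expect_equal(round(100 * 0.0731 * 0.8079 / 0.1211, 2), 48.77)
  # media-exposure row: contribution 0.013407 -> 11.07% of 0.1211
  expect_equal(round(100 * 0.013407 / 0.1211, 2), 11.07)
  # post-natal row: negative contribution -0.0081 -> -6.69%
  expect_equal(round(100 * -0.0081 / 0.1211, 2), -6.69)
  # higher-education row of the education-ranked table
  expect_equal(round(0.1093 * 0.8206, 4), 0.0897)
})

test_that("percentage finalisation guards against a null overall index", {
  coh <- make_cohort(tiny_config(n = 1000, seed = 83))
  fr <- weighted_fractional_rank(coh$wealth_quintile, coh$weight)
  overall <- concentration_index(coh$mdd, fr, coh$weight)
  fit <- fit_lpm(coh, "mdd")
  dec <- decompose_cix(fit, fr, coh$weight, overall)
  dec$overall <- 0
  expect_error(percentage_contributions(dec), "undefined")
})

test_that("the table verifier flags a deliberately corrupted row", {
  path <- system.file("extdata", "published_decomposition_wealth.csv",
                      package = "mddineq", mustWork = TRUE)
  pub <- read_published_decomposition(path)
  rep0 <- verify_published_table(pub)
  bad <- pub
  i <- which(bad$variable == "wealth_quintile" & bad$category == "richest")
  bad$contribution[i] <- "0.0791" # corrupt: 0.0731 x 0.8079 is nowhere near
  rep1 <- verify_published_table(bad)
  flagged <- rep1[!rep1$agree, ]
  expect_true(any(flagged$variable == "wealth_quintile" & flagged$category == "richest"))
  expect_gt(attr(rep1, "n_flagged"), attr(rep0, "n_flagged"))
})

test_that("the unweighted-regression flag changes the fit", {
  coh <- make_cohort(tiny_config(n = 1500, seed = 84))
  f_w <- fit_lpm(coh, "mdd")
  f_u <- fit_lpm(coh, "mdd", weighted = FALSE)
  expect_false(isTRUE(all.equal(f_w$beta, f_u$beta, tolerance = 1e-8)))
  # xbar stays survey-weighted in both
  expect_equal(f_w$xbar, f_u$xbar, tolerance = 1e-12)
})
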