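test_that("fractional ranks are cumulative-weight midpoints with shared ties", {
  expect_equal(weighted_fractional_rank(c(10, 20, 30, 40), rep(1, 4))$rank,
               c(0.125, 0.375, 0.625, 0.875))
  expect_equal(weighted_fractional_rank(rep(1, 6), runif(6) + 0.5)$rank, rep(0.5, 6))
  # weights (1, 3) over two ordered groups: 0 + 0.25/2 and 0.25 + 0.75/2
  expect_equal(weighted_fractional_rank(c(1, 2), c(1, 3))$rank, c(0.125, 0.625))

  fr <- weighted_fractional_rank(factor(c("b", "a", "b"), levels = c("a", "b"), ordered = TRUE),
                                 c(1, 1, 2))
  expect_equal(fr$rank, c(0.625, 0.125, 0.625))
})

test_that("ranks refuse unordered categoricals and missing values", {
  expect_error(weighted_fractional_rank(c("x", "y"), c(1, 1)), "declared order")
  expect_error(weighted_fractional_rank(factor(c("x", "y")), c(1, 1)), "declared order")
  expect_error(weighted_fractional_rank(c(1, NA), c(1, 1)), "missing")
  expect_error(weighted_fractional_rank(c(1, 2), c(1, -1)), "positive")
  # a declared order makes characters rankable
  expect_equal(weighted_fractional_rank(c("hi", "lo"), c(1, 1),
                                        order_levels = c("lo", "hi"))$rank,
               c(0.75, 0.25))
})

test_that("weighted mean rank is 0.5 across random tie structures", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    x <- sample(1:6, n, replace = TRUE)
    w <- rexp(n) + 0.1
    fr <- weighted_fractional_rank(x, w)
    expect_lt(abs(sum(w / sum(w) * fr$rank) - 0.5), 1e-12)
    # ranks constant within tie groups, increasing across them
    expect_true(all(tapply(fr$rank, x, function(r) max(r) - min(r)) == 0))
    expect_true(all(diff(fr$groups$rank) > 0))
  }
})

test_that("the hand-worked binary example attains the upper bound 1 - mu", {
  r <- weighted_fractional_rank(1:4, rep(1, 4))
  est <- concentration_index(c(0, 0, 1, 1), r, rep(1, 4))
  expect_equal(est$value, 0.5, tolerance = 1e-12)
  expect_equal(est$mu, 0.5)
  expect_equal(est$value, 1 - est$mu, tolerance = 1e-12) # binary upper bound, exactly attained
})

test_that("a constant outcome and degenerate subgroups carry no concentration", {
  r <- weighted_fractional_rank(1:5, rep(1, 5))
  expect_equal(concentration_index(rep(1, 5), r, rep(1, 5))$value, 0)
  expect_error(concentration_index(rep(0, 5), r, rep(1, 5)), "undefined")
  # single observation: covariance with its own rank (0.5) vanishes
  one <- concentration_index(1, weighted_fractional_rank(3, 2), 2)
  expect_equal(one$value, 0)
  expect_true(is.na(one$se))
})

test_that("the covariance formula matches the brute-force expansion to 1e-12", {
  set.seed(303)
  for (i in 1:15) {
    n <- sample(10:200, 1)
    x <- sample(1:5, n, replace = TRUE)
    w <- rexp(n) + 0.1
    h <- rbinom(n, 1, plogis(-0.5 + 0.3 * x))
    if (sum(h) == 0) h[1] <- 1
    fr <- weighted_fractional_rank(x, w)
    est <- concentration_index(h, fr, w)
    expect_lt(abs(est$value - cix_bruteforce(h, fr$rank, w)), 1e-12)
    # binary bound
    expect_gte(est$value, est$mu - 1 - 1e-12)
    expect_lte(est$value, 1 - est$mu + 1e-12)
    expect_true(abs(est$value) <= 1)
  }
})

test_that("the index is scale invariant and antisymmetric in the ranking order", {
  set.seed(44)
  n <- 120
  x <- sample(1:5, n, replace = TRUE)
  w <- rexp(n) + 0.1
  h <- rbinom(n, 1, 0.2 + 0.1 * x)
  fr <- weighted_fractional_rank(x, w)
  est <- concentration_index(h, fr, w)

  expect_equal(concentration_index(7.3 * h, fr, w)$value, est$value, tolerance = 1e-12)

  rev_fr <- weighted_fractional_rank(-x, w)
  expect_equal(concentration_index(h, rev_fr, w)$value, -est$value, tolerance = 1e-12)
})

test_that("concentration curves anchor at the corners and integrate back to the index", {
  # outcome identically distributed across groups: the curve is the diagonal
  flat <- concentration_curve(rep(1, 10), rep(1:5, 2), rep(1, 10))
  expect_equal(flat$points$outcome_share, flat$points$pop_share, tolerance = 1e-12)
  # the curve passes through the midpoint (0.5, 0.5) of the equality line
  expect_equal(approx(flat$points$pop_share, flat$points$outcome_share, 0.5)$y, 0.5,
               tolerance = 1e-12)
  expect_false(flat$below_diagonal || flat$above_diagonal)

  # all MDD in the top quintile, equal weights: last interior point (0.8, 0)
  h <- rep(c(0, 0, 0, 0, 1), each = 4)
  top <- concentration_curve(h, rep(1:5, each = 4), rep(1, 20))
  expect_equal(top$points$pop_share, c(0, 0.2, 0.4, 0.6, 0.8, 1))
  expect_equal(top$points$outcome_share[5], 0)
  expect_true(top$below_diagonal)

  # twice the diagonal-curve area reproduces the covariance index exactly
  set.seed(55)
  for (i in 1:10) {
    n <- sample(20:150, 1)
    x <- sample(1:5, n, replace = TRUE)
    w <- rexp(n) + 0.1
    h <- rbinom(n, 1, 0.15 + 0.12 * x)
    if (sum(h) == 0) h[1] <- 1
    cv <- concentration_curve(h, x, w)
    fr <- weighted_fractional_rank(x, w)
    expect_equal(cv$cix_from_area, concentration_index(h, fr, w)$value,
                 tolerance = 1e-12)
    expect_true(all(diff(cv$points$pop_share) >= 0))
    expect_true(all(diff(cv$points$outcome_share) >= -1e-15))
  }
})

test_that("subgroup indices recover age-band-specific inequality structure", {
  # gradient confined to the 6-12 month band: that band's CIX is largest
  cfg <- tiny_config(n = 40000, seed = 61,
                     wealth_gradient = c(-0.12, -0.06, 0, 0.06, 0.12),
                     education_gradient = rep(0, 4),
                     age_band_scale = c(1, 0, 0))
  coh <- make_cohort(cfg)
  sg <- subgroup_cix(coh, "mdd", "wealth_quintile", "child_age_band")
  expect_equal(attr(sg, "largest"), "6-12")
  expect_gt(sg$cix[sg$subgroup == "6-12"], max(sg$cix[sg$subgroup != "6-12"]))

  # exchangeable bands: indices agree within Monte-Carlo error
  cfg2 <- tiny_config(n = 40000, seed = 62,
                      wealth_gradient = c(-0.08, -0.04, 0, 0.04, 0.08))
  sg2 <- subgroup_cix(make_cohort(cfg2), "mdd", "wealth_quintile", "child_age_band")
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(abs(sg2$cix[i] - sg2$cix[j]), 3 * sqrt(sg2$se[i]^2 + sg2$se[j]^2))
  }

  # a subgroup that never experiences the outcome is flagged and excluded
  toy <- data.frame(mdd = c(0, 0, 1, 1), wq = c(1, 2, 1, 2),
                    grp = factor(c("a", "a", "b", "b")), weight = 1)
  sg3 <- subgroup_cix(toy, "mdd", "wq", "grp", cluster = NULL)
  expect_false(sg3$defined[sg3$subgroup == "a"])
  expect_equal(attr(sg3, "largest"), "b")
})

test_that("component food-group indices recover injected sign structure", {
  # breastfeeding declines with wealth; dairy rises steeply (the defaults)
  coh <- make_cohort(generator_config(n_children = 20000, seed = 63, missing_rate = 0))
  comp <- component_cix(coh, "wealth_quintile")
  expect_equal(nrow(comp), 8L)
  expect_lt(comp$cix[comp$food_group == "breastfeeding"], 0)
  expect_lt(comp$p_value[comp$food_group == "breastfeeding"], 0.05)
  expect_gt(comp$cix[comp$food_group == "dairy"], 0)
  expect_lt(comp$p_value[comp$food_group == "dairy"], 0.05)
  # grains carry no wealth gradient by default: index near zero
  expect_lt(abs(comp$cix[comp$food_group == "grains"]),
            3 * comp$se[comp$food_group == "grains"] + 0.01)

  # degenerate components
  toy <- coh[1:50, ]
  toy$fg_grains <- 1L
  toy$fg_eggs <- 0L
  comp2 <- component_cix(toy, "wealth_quintile")
  expect_equal(comp2$cix[comp2$food_group == "grains"], 0)
  expect_false(comp2$defined[comp2$food_group == "eggs"])
})

test_that("a flat food group is rarely declared significant (size control)", {
  # type-I error of the component test at alpha = 0.05 across seeds
  nonsig <- 0
  R <- 40
  for (i in seq_len(R)) {
    coh <- make_cohort(tiny_config(n = 700, seed = 7000 + i,
                                   wealth_gradient = rep(0, 5),
                                   education_gradient = rep(0, 4)),
                       covariates = c("wealth_quintile", "mother_education"))
    fr <- weighted_fractional_rank(coh$wealth_quintile, coh$weight)
    est <- concentration_index(coh$fg_grains, fr, coh$weight,
                               cluster = coh$cluster_id)
    nonsig <- nonsig + (est$p_value >= 0.05)
  }
  expect_gte(nonsig / R, 0.85)
})
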