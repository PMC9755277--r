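#' Configuration for the synthetic DHS-style survey generator
#'
#' Defines the data-generating conditions for a child-recode-like table:
#' one row per child aged 0--35 months with sampling weight, survey-design
#' identifiers, the eight binary food-group indicators, and the
#' socio-demographic covariates used in the inequality analysis. Food-group
#' consumption probabilities are additive in a per-quintile wealth offset
#' and a per-level maternal-education offset on the probability scale:
#' `p[g] = clip(base[g] + wealth_gradient[q, g] + education_gradient[e, g], 0, 1)`.
#'
#' @param n_children number of children (rows) to generate.
#' @param seed integer RNG seed; the whole table is a deterministic function
#'   of the config.
#' @param base_group_probs length-8 vector of baseline consumption
#'   probabilities, ordered as [food_group_columns()].
#' @param wealth_gradient per-quintile probability offsets: either a length-5
#'   vector (applied to all 8 groups) or a 5 x 8 matrix (quintile x group).
#' @param education_gradient per-education-level offsets: length-4 vector or
#'   4 x 8 matrix.
#' @param education_by_wealth 5 x 4 row-stochastic matrix giving the
#'   distribution of maternal education within each wealth quintile; the
#'   default encodes the mild positive wealth-education association seen in
#'   DHS data. Use a matrix with identical rows for independence.
#' @param weight_dispersion coefficient of variation of the log-normal
#'   sampling weights (0 = equal weights); weights are rescaled to mean 1.
#' @param target_prevalence if non-`NULL`, an additive logit shift applied to
#'   `base_group_probs` is solved by bisection so that the analytic weighted
#'   MDD prevalence among children aged 6--23 months equals this value.
#' @param missing_rate per-field probability of a missing value (MCAR) on
#'   the food-group flags and on a subset of covariate fields.
#' @param age_band_scale length-3 multiplier applied to the combined
#'   wealth/education offsets within child age bands 6--12, 13--18 and 19--23
#'   months (children outside 6--23 use scale 1). `c(1, 1, 1)` makes the
#'   SES gradient exchangeable across age bands.
#' @param n_clusters total number of primary sampling units; default one per
#'   ~30 children, mirroring DHS cluster takes.
#' @param n_strata number of design strata; the default 16 is realised as
#'   division x residence, any other value assigns households to strata
#'   round-robin.
#' @return an object of class `generator_config` (a named list).
#' @seealso [generate_survey()], [true_decomposition()],
#'   [analytic_mdd_prevalence()]
#' @export
generator_config <- function(n_children = 6000L,
                             seed = 1L,
                             base_group_probs = c(
                               breastfeeding = 0.87, grains = 0.82,
                               legumes = 0.22, dairy = 0.28, flesh = 0.48,
                               eggs = 0.30, vita_fruit_veg = 0.42,
                               other_fruit_veg = 0.33),
                             wealth_gradient = default_wealth_gradient(),
                             education_gradient = default_education_gradient(),
                             education_by_wealth = default_education_by_wealth(),
                             weight_dispersion = 0.5,
                             target_prevalence = 0.3747,
                             missing_rate = 0.02,
                             age_band_scale = c(1, 1, 1),
                             n_clusters = NULL,
                             n_strata = 16L) {
  cfg <- list(
    n_children = n_children, seed = seed,
    base_group_probs = unname(base_group_probs),
    wealth_gradient = expand_gradient(wealth_gradient, 5L, "wealth_gradient"),
    education_gradient = expand_gradient(education_gradient, 4L, "education_gradient"),
    education_by_wealth = education_by_wealth,
    weight_dispersion = weight_dispersion,
    target_prevalence = target_prevalence,
    missing_rate = missing_rate,
    age_band_scale = age_band_scale,
    n_clusters = n_clusters %||% max(1L, as.integer(ceiling(n_children / 30))),
    n_strata = as.integer(n_strata)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

# Default SES gradients: symmetric probability offsets around the middle
# quintile / mid education. Breastfeeding declines with SES (the classic
# reverse gradient); dairy, eggs, flesh and fruit/vegetable groups rise.
default_wealth_gradient <- function() {
  slopes <- c(breastfeeding = -0.03, grains = 0.00, legumes = 0.02,
              dairy = 0.10, flesh = 0.06, eggs = 0.06,
              vita_fruit_veg = 0.04, other_fruit_veg = 0.04)
  outer(seq(-1, 1, length.out = 5), unname(slopes))
}

default_education_gradient <- function() {
  slopes <- c(breastfeeding = -0.02, grains = 0.01, legumes = 0.02,
              dairy = 0.08, flesh = 0.05, eggs = 0.05,
              vita_fruit_veg = 0.05, other_fruit_veg = 0.04)
  outer(seq(-1, 1, length.out = 4), unname(slopes))
}

default_education_by_wealth <- function() {
  m <- rbind(
    poorest = c(0.14, 0.38, 0.42, 0.06),
    poorer  = c(0.09, 0.33, 0.49, 0.09),
    middle  = c(0.06, 0.28, 0.52, 0.14),
    richer  = c(0.04, 0.22, 0.52, 0.22),
    richest = c(0.02, 0.14, 0.46, 0.38))
  colnames(m) <- EDU_LEVELS
  m
}

expand_gradient <- function(g, n_levels, field) {
  if (is.matrix(g)) {
    if (!identical(dim(g), c(n_levels, 8L)) && !identical(dim(g), as.integer(c(n_levels, 8)))) {
      stop(sprintf("generator_config: `%s` matrix must be %d x 8", field, n_levels),
           call. = FALSE)
    }
    return(unname(g))
  }
  if (length(g) != n_levels) {
    stop(sprintf("generator_config: `%s` must have length %d (or be a %d x 8 matrix)",
                 field, n_levels, n_levels), call. = FALSE)
  }
  matrix(rep(as.numeric(g), 8L), nrow = n_levels)
}

validate_generator_config <- function(cfg) {
  bad <- function(field, msg) {
    stop(sprintf("generator_config: `%s` %s", field, msg), call. = FALSE)
  }
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(cfg$n_children) || length(cfg$n_children) != 1 || cfg$n_children < 1 ||
      cfg$n_children != round(cfg$n_children)) {
    bad("n_children", "must be a positive integer")
  }
  if (!num_ok(cfg$seed) || length(cfg$seed) != 1) bad("seed", "must be a finite number")
  if (!num_ok(cfg$base_group_probs) || length(cfg$base_group_probs) != 8 ||
      any(cfg$base_group_probs < 0) || any(cfg$base_group_probs > 1)) {
    bad("base_group_probs", "must be 8 probabilities in [0, 1]")
  }
  if (!num_ok(cfg$wealth_gradient)) bad("wealth_gradient", "must be finite")
  if (!num_ok(cfg$education_gradient)) bad("education_gradient", "must be finite")
  ebw <- cfg$education_by_wealth
  if (!is.matrix(ebw) || nrow(ebw) != 5 || ncol(ebw) != 4 || !num_ok(ebw) ||
      any(ebw < 0) || any(abs(rowSums(ebw) - 1) > 1e-8)) {
    bad("education_by_wealth", "must be a 5 x 4 matrix of row-stochastic probabilities")
  }
  if (!num_ok(cfg$weight_dispersion) || cfg$weight_dispersion < 0) {
    bad("weight_dispersion", "must be >= 0")
  }
  if (!is.null(cfg$target_prevalence)) {
    tp <- cfg$target_prevalence
    if (!num_ok(tp) || length(tp) != 1 || tp <= 0 || tp >= 1) {
      bad("target_prevalence", "must lie strictly inside (0, 1)")
    }
    if (any(cfg$base_group_probs <= 0) || any(cfg$base_group_probs >= 1)) {
      bad("base_group_probs", "must lie strictly inside (0, 1) when target_prevalence is set")
    }
  }
  if (!num_ok(cfg$missing_rate) || cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    bad("missing_rate", "must lie in [0, 1)")
  }
  if (!num_ok(cfg$age_band_scale) || length(cfg$age_band_scale) != 3) {
    bad("age_band_scale", "must be a length-3 numeric vector")
  }
  if (!num_ok(cfg$n_clusters) || cfg$n_clusters < 1) bad("n_clusters", "must be >= 1")
  if (!num_ok(cfg$n_strata) || cfg$n_strata < 1) bad("n_strata", "must be >= 1")
  invisible(cfg)
}

# Exact distribution of the number of food groups consumed: probability that
# a sum of 8 independent Bernoulli(p_g) variables reaches the MDD threshold.
poisson_binomial_tail <- function(p, threshold = 5L) {
  pmf <- 1
  for (pg in p) pmf <- c(pmf * (1 - pg), 0) + c(0, pmf * pg)
  sum(pmf[(threshold + 1L):length(pmf)])
}

# Conditional distribution of child age band given 6-23 months, for a
# uniform age draw over 0-35 months: bands 6-12, 13-18, 19-23 span 7, 6 and
# 5 months respectively.
BAND_SHARES <- c(7, 6, 5) / 18

# Effective per-cell consumption probabilities. Returns the logit-shifted
# baseline, the raw additive offsets O[q, e, g], and the shift delta.
effective_group_probs <- function(cfg) {
  offsets <- array(0, dim = c(5, 4, 8))
  for (q in 1:5) {
    for (e in 1:4) {
      offsets[q, e, ] <- cfg$wealth_gradient[q, ] + cfg$education_gradient[e, ]
    }
  }
  delta <- 0
  if (!is.null(cfg$target_prevalence)) {
    f <- function(d) analytic_prevalence_delta(cfg, offsets, d) - cfg$target_prevalence
    lo <- f(-12); hi <- f(12)
    if (lo > 0 || hi < 0) {
      stop("generator_config: `target_prevalence` is unreachable under the configured gradients",
           call. = FALSE)
    }
    delta <- uniroot(f, c(-12, 12), tol = 1e-12)$root
  }
  base <- plogis(qlogis(cfg$base_group_probs) + delta)
  list(base = base, offsets = offsets, delta = delta)
}

cell_weights <- function(cfg) {
  # joint P(quintile, education): quintiles are exact weighted fifths
  sweep(cfg$education_by_wealth, 1, 0.2, `*`)
}

analytic_prevalence_delta <- function(cfg, offsets, delta) {
  base <- plogis(qlogis(cfg$base_group_probs) + delta)
  pqe <- cell_weights(cfg)
  prev <- 0
  for (b in 1:3) {
    s <- cfg$age_band_scale[b]
    for (q in 1:5) {
      for (e in 1:4) {
        p <- clip01(base + s * offsets[q, e, ])
        prev <- prev + BAND_SHARES[b] * pqe[q, e] * poisson_binomial_tail(p)
      }
    }
  }
  prev
}

#' Analytic weighted MDD prevalence implied by a generator configuration
#'
#' Closed-form expectation over the finite (age band x wealth quintile x
#' maternal education) grid of the probability that a child aged 6--23
#' months consumes at least 5 of 8 food groups, using the exact
#' Poisson-binomial tail in each cell. The empirical weighted prevalence of
#' a generated cohort converges to this value as `n_children` grows.
#'
#' @param config a [generator_config()].
#' @return scalar prevalence (proportion).
#' @export
analytic_mdd_prevalence <- function(config) {
  validate_generator_config(config)
  eg <- effective_group_probs(config)
  analytic_prevalence_delta(config, eg$offsets,
                            eg$delta) # base shift already solved; recompute at delta
}

#' Generate a synthetic DHS-style child-recode survey table
#'
#' Draws a reproducible child-level table with unequal sampling weights,
#' cluster/stratum identifiers, household asset indicators, raw covariate
#' fields (media sources, ANC visit counts, parity) and the eight food-group
#' flags. Wealth quintiles are exact weighted fifths of a latent household
#' wealth score; maternal education is drawn conditionally on the quintile;
#' food-group flags are independent Bernoulli draws with the additive
#' SES-gradient probabilities of the configuration.
#'
#' @param config a [generator_config()].
#' @return a `data.frame` with one row per child; the configuration is
#'   attached as attribute `"generator_config"`. Missing values are `NA`.
#' @examples
#' tab <- generate_survey(generator_config(n_children = 500, seed = 7))
#' nrow(tab)
#' @export
generate_survey <- function(config = generator_config()) {
  validate_generator_config(config)
  eg <- effective_group_probs(config)
  set.seed(config$seed)
  n <- as.integer(config$n_children)

  # households: a small fraction contribute two children in the recode
  n2 <- floor(0.09 * n / 2)
  n_hh <- n - n2
  hh_sizes <- c(rep(2L, n2), rep(1L, n_hh - n2))
  hh <- rep.int(seq_len(n_hh), hh_sizes)

  # latent household wealth and asset indicators loading on it
  z <- rnorm(n_hh)
  assets <- data.frame(
    asset_electricity    = rbinom(n_hh, 1, plogis(1.2 + 1.6 * z)),
    asset_tv             = rbinom(n_hh, 1, plogis(0.1 + 1.5 * z)),
    asset_refrigerator   = rbinom(n_hh, 1, plogis(-0.9 + 1.7 * z)),
    asset_mobile_phone   = rbinom(n_hh, 1, plogis(1.8 + 0.8 * z)),
    asset_motorcycle     = rbinom(n_hh, 1, plogis(-1.7 + 1.1 * z)),
    asset_improved_floor = rbinom(n_hh, 1, plogis(-0.4 + 1.8 * z)),
    asset_improved_roof  = rbinom(n_hh, 1, plogis(1.0 + 1.2 * z)),
    asset_improved_toilet = rbinom(n_hh, 1, plogis(0.3 + 1.3 * z)),
    asset_rooms_per_person = exp(-1 + 0.35 * z + rnorm(n_hh, sd = 0.3)),
    asset_land_acres     = exp(-1.5 + 0.5 * z + rnorm(n_hh, sd = 0.8))
  )

  # sampling weights: log-normal with the requested CV, rescaled to mean 1
  if (config$weight_dispersion > 0) {
    s2 <- log(1 + config$weight_dispersion^2)
    weight <- exp(rnorm(n, -s2 / 2, sqrt(s2)))
    weight <- weight / mean(weight)
  } else {
    weight <- rep(1, n)
  }

  # wealth quintiles: exact weighted fifths of the latent household score
  q <- weighted_quantile_groups(z[hh], weight)
  hh_q <- q[match(seq_len(n_hh), hh)]

  # maternal education conditional on the household's quintile
  e_hh <- integer(n_hh)
  for (qq in 1:5) {
    idx <- which(hh_q == qq)
    if (length(idx)) {
      e_hh[idx] <- sample.int(4L, length(idx), replace = TRUE,
                              prob = config$education_by_wealth[qq, ])
    }
  }
  ec <- (e_hh - 2.5) / 1.5   # centred/scaled education, household level
  qc <- (hh_q - 3) / 2       # centred/scaled quintile

  # partner education: noisy ordinal shift around the mother's level
  shift_probs <- rbind(c(0.55, 0.30, 0.12, 0.03),
                       c(0.20, 0.45, 0.28, 0.07),
                       c(0.06, 0.26, 0.50, 0.18),
                       c(0.02, 0.10, 0.38, 0.50))
  pe_hh <- integer(n_hh)
  for (ee in 1:4) {
    idx <- which(e_hh == ee)
    if (length(idx)) {
      pe_hh[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = shift_probs[ee, ])
    }
  }

  mother_age_hh <- sample(MOTHER_AGE_LEVELS, n_hh, replace = TRUE,
                          prob = c(0.1917, 0.3521, 0.2483, 0.2079))
  division_hh <- sample(DIVISIONS, n_hh, replace = TRUE,
                        prob = c(0.0582, 0.2026, 0.2558, 0.0886,
                                 0.0857, 0.1152, 0.1140, 0.0798))
  urban_hh <- rbinom(n_hh, 1, plogis(qlogis(0.26) + 0.40 * z))
  residence_hh <- RESIDENCE_LEVELS[urban_hh + 1L]

  # raw media-source fields (weekly exposure), SES-graded
  newspaper_hh <- rbinom(n_hh, 1, plogis(-3.0 + 1.0 * (e_hh - 1)))
  tv_hh <- rbinom(n_hh, 1, plogis(-0.3 + 0.9 * qc + 0.3 * ec))
  radio_hh <- rbinom(n_hh, 1, plogis(-2.8 + 0.2 * ec))
  working_hh <- rbinom(n_hh, 1, 0.368)
  postnatal_hh <- rbinom(n_hh, 1, plogis(0.63 + 0.25 * qc + 0.15 * ec))
  anc_hh <- rpois(n_hh, exp(1.25 + 0.12 * qc + 0.18 * ec))
  living_hh <- sample(1:5, n_hh, replace = TRUE,
                      prob = c(0.392, 0.348, 0.16, 0.07, 0.03))

  # strata and clusters (clusters nested in strata, assigned per household)
  if (config$n_strata == 16L) {
    stratum_hh <- paste(division_hh, residence_hh, sep = "_")
  } else {
    stratum_hh <- sprintf("stratum_%02d", (seq_len(n_hh) %% config$n_strata) + 1L)
  }
  strata <- sort(unique(stratum_hh))
  tab_s <- table(stratum_hh)
  k_s <- pmax(1L, round(config$n_clusters * as.numeric(tab_s) / n_hh))
  cluster_hh <- character(n_hh)
  for (i in seq_along(strata)) {
    idx <- which(stratum_hh == strata[i])
    cluster_hh[idx] <- sprintf("%s_c%03d", strata[i],
                               sample.int(k_s[i], length(idx), replace = TRUE))
  }

  # child-level fields
  child_age <- sample(0:35, n, replace = TRUE)
  child_sex <- SEX_LEVELS[rbinom(n, 1, 1 - 0.5181) + 1L]

  # food-group flags: additive SES gradient, scaled by the child's age band
  band <- age_band_index(child_age)
  scale <- ifelse(is.na(band), 1, config$age_band_scale[band])
  e_child <- e_hh[hh]
  probs <- matrix(eg$base, n, 8, byrow = TRUE) +
    scale * eg$offsets[cbind(rep(q, 8), rep(e_child, 8), rep(1:8, each = n))]
  probs <- clip01(matrix(probs, n, 8))
  fg <- matrix(rbinom(n * 8L, 1L, probs), n, 8)
  colnames(fg) <- food_group_columns()

  out <- data.frame(
    child_id = sprintf("c%06d", seq_len(n)),
    household_id = sprintf("h%05d", hh),
    cluster_id = cluster_hh[hh],
    stratum_id = stratum_hh[hh],
    weight = weight,
    child_age_months = child_age,
    child_sex = factor(child_sex, SEX_LEVELS),
    fg,
    wealth_quintile = factor(WEALTH_LEVELS[q], WEALTH_LEVELS, ordered = TRUE),
    mother_education = factor(EDU_LEVELS[e_child], EDU_LEVELS, ordered = TRUE),
    partner_education = factor(EDU_LEVELS[pe_hh[hh]], EDU_LEVELS, ordered = TRUE),
    mother_age_group = factor(mother_age_hh[hh], MOTHER_AGE_LEVELS),
    residence = factor(residence_hh[hh], RESIDENCE_LEVELS),
    newspaper_weekly = newspaper_hh[hh],
    tv_weekly = tv_hh[hh],
    radio_weekly = radio_hh[hh],
    currently_working = factor(YESNO[working_hh[hh] + 1L], YESNO),
    postnatal_visited = factor(YESNO[postnatal_hh[hh] + 1L], YESNO),
    anc_visits = anc_hh[hh],
    living_children = living_hh[hh],
    division = factor(division_hh[hh], DIVISIONS),
    assets[hh, , drop = FALSE],
    row.names = NULL,
    check.names = FALSE
  )

  # MCAR missingness on outcome flags and a subset of covariate fields
  if (config$missing_rate > 0) {
    missable <- c(food_group_columns(), "anc_visits", "postnatal_visited",
                  "newspaper_weekly", "tv_weekly", "radio_weekly",
                  "currently_working", "partner_education")
    for (cl in missable) {
      out[[cl]][runif(n) < config$missing_rate] <- NA
    }
  }

  attr(out, "generator_config") <- config
  out
}

age_band_index <- function(age_months) {
  b <- rep(NA_integer_, length(age_months))
  b[age_months >= 6 & age_months <= 12] <- 1L
  b[age_months >= 13 & age_months <= 18] <- 2L
  b[age_months >= 19 & age_months <= 23] <- 3L
  b
}

#' Analytic decomposition implied by a generator configuration
#'
#' Brute-force expectation over the finite (wealth quintile x maternal
#' education x age band) grid: the cell-level MDD probabilities are
#' projected by weighted least squares onto the wealth and education dummy
#' design, giving the asymptotic elasticities, component concentration
#' indices, contributions and shares that the sample decomposition
#' ([fit_lpm()] + [decompose_cix()] on `~ wealth + education`) recovers as
#' `n_children` grows. This is the generator's parameter-recovery oracle.
#'
#' Only clipping-free configurations are supported: if any cell probability
#' `base + offsets` leaves `[0, 1]`, additivity is distorted and the
#' function refuses with an error of class `mddineq_clipping_error`.
#'
#' @param config a [generator_config()].
#' @param ranking `"wealth_quintile"` or `"mother_education"`: the ranking
#'   variable of the concentration index being decomposed.
#' @return a list with elements `rows` (per-dummy elasticity, `C_k`,
#'   contribution, share), `variable_shares` (per-variable contribution
#'   share of the overall index), `cix`, `mu`, `explained`, `residual`.
#' @export
true_decomposition <- function(config, ranking = c("wealth_quintile", "mother_education")) {
  ranking <- match.arg(ranking)
  validate_generator_config(config)
  eg <- effective_group_probs(config)

  # grid over quintile x education x age band (cohort = children 6-23 months)
  grid <- expand.grid(q = 1:5, e = 1:4, b = 1:3)
  pqe <- cell_weights(config)
  grid$w <- pqe[cbind(grid$q, grid$e)] * BAND_SHARES[grid$b]

  m <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    praw <- eg$base + config$age_band_scale[grid$b[i]] * eg$offsets[grid$q[i], grid$e[i], ]
    if (any(praw < -1e-12) || any(praw > 1 + 1e-12)) {
      stop(structure(class = c("mddineq_clipping_error", "error", "condition"),
                     list(message = paste(
                       "true_decomposition: configuration is not clipping-free;",
                       "cell probabilities leave [0, 1] and additivity is distorted"),
                       call = NULL)))
    }
    m[i] <- poisson_binomial_tail(clip01(praw))
  }
  mu <- sum(grid$w * m)

  # fractional ranks over the ranking variable's marginal distribution
  if (ranking == "wealth_quintile") {
    shares <- rep(0.2, 5)
    r_of <- function(g) group_midpoint_ranks(shares)[g$q]
  } else {
    shares <- colSums(pqe)
    r_of <- function(g) group_midpoint_ranks(shares)[g$e]
  }
  r <- r_of(grid)

  # dummy design: wealth (ref poorest) + education (ref none)
  X <- cbind(
    `wealth_quintile:poorer`  = as.numeric(grid$q == 2),
    `wealth_quintile:middle`  = as.numeric(grid$q == 3),
    `wealth_quintile:richer`  = as.numeric(grid$q == 4),
    `wealth_quintile:richest` = as.numeric(grid$q == 5),
    `mother_education:primary`   = as.numeric(grid$e == 2),
    `mother_education:secondary` = as.numeric(grid$e == 3),
    `mother_education:higher`    = as.numeric(grid$e == 4)
  )
  fit <- stats::lm.wfit(cbind(`(Intercept)` = 1, X), m, grid$w)
  beta <- fit$coefficients[-1]

  xbar <- colSums(grid$w * X)
  ck <- vapply(seq_len(ncol(X)),
               function(k) 2 * wcov(X[, k], r, grid$w) / xbar[k], numeric(1))
  elasticity <- beta * xbar / mu
  contribution <- elasticity * ck
  cix <- 2 * wcov(m, r, grid$w) / mu
  explained <- sum(contribution)
  residual <- cix - explained

  variable <- sub(":.*$", "", colnames(X))
  rows <- data.frame(
    variable = variable,
    category = sub("^.*:", "", colnames(X)),
    elasticity = elasticity, c_k = ck, contribution = contribution,
    share = if (abs(cix) > 0) contribution / cix else 0,
    row.names = NULL
  )
  vs <- tapply(rows$contribution, rows$variable, sum)
  list(rows = rows,
       variable_shares = if (abs(cix) > 0) vs / cix else vs * 0,
       cix = cix, mu = mu, explained = explained, residual = residual)
}

group_midpoint_ranks <- function(shares) {
  hi <- cumsum(shares)
  hi - shares / 2
}

#' Write a survey table as CSV with a config snapshot
#'
#' Missing values are written as empty fields. If the table carries its
#' generator configuration, a YAML snapshot is written alongside the CSV
#' (`<path>.config.yaml`) so the run can be regenerated.
#'
#' @param table a survey table (from [generate_survey()] or compatible).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  cfg <- attr(table, "generator_config")
  if (!is.null(cfg)) {
    snap <- lapply(unclass(cfg), function(x) {
      if (is.matrix(x)) apply(x, 1, as.numeric, simplify = FALSE) else x
    })
    yaml::write_yaml(snap, paste0(path, ".config.yaml"))
  }
  invisible(path)
}

#' Read a survey table written by [write_survey_csv()]
#'
#' Restores the canonical factor codings of [covariate_levels()]; empty
#' fields become `NA`.
#'
#' @param path CSV path.
#' @return a `data.frame`.
#' @export
read_survey_csv <- function(path) {
  tab <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  lv <- covariate_levels()
  ordered_cols <- c("wealth_quintile", "mother_education", "partner_education")
  for (cl in intersect(names(lv), names(tab))) {
    tab[[cl]] <- factor(tab[[cl]], levels = lv[[cl]], ordered = cl %in% ordered_cols)
  }
  tab
}
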