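#' Weighted fractional ranks with tie-group midpoints
#'
#' Each observation's fractional rank is its position in the weighted
#' cumulative distribution of the ranking variable: with weights normalised
#' to sum 1 and tie groups ordered, a tie group's shared rank is the
#' cumulative weight of all strictly lower groups plus half its own weight.
#' The weighted mean of the ranks is exactly 0.5.
#'
#' @param x ranking variable: numeric, ordered factor, or (with
#'   `order_levels`) character/factor. An unordered categorical variable
#'   without a declared order is refused.
#' @param w strictly positive weights.
#' @param order_levels optional character vector declaring the category
#'   order from lowest to highest.
#' @param variable optional name recorded on the result.
#' @return an object of class `fractional_rank`: list with `rank` (numeric
#'   vector in (0, 1)), `variable`, and `groups` (per tie group: value,
#'   weighted share, shared rank).
#' @examples
#' weighted_fractional_rank(c(1, 2, 3, 4), rep(1, 4))$rank
#' @export
weighted_fractional_rank <- function(x, w, order_levels = NULL, variable = NULL) {
  variable <- variable %||% deparse(substitute(x))[1]
  assert_positive_weights(w)
  assert_same_length(x, w, what = "`x` and `w`")
  if (anyNA(x)) stop("weighted_fractional_rank: ranking variable has missing values", call. = FALSE)

  if (!is.null(order_levels)) {
    x <- factor(as.character(x), levels = order_levels)
    if (anyNA(x)) {
      stop("weighted_fractional_rank: values outside `order_levels`", call. = FALSE)
    }
    codes <- as.integer(x)
    labels <- order_levels
  } else if (is.ordered(x)) {
    codes <- as.integer(x)
    labels <- levels(x)
  } else if (is.numeric(x) || is.logical(x)) {
    u <- sort(unique(as.numeric(x)))
    codes <- match(as.numeric(x), u)
    labels <- as.character(u)
  } else {
    stop(paste("weighted_fractional_rank: categorical ranking variable without a",
               "declared order; pass `order_levels` or an ordered factor"), call. = FALSE)
  }

  wn <- w / sum(w)
  grp_w <- vapply(seq_along(labels), function(g) sum(wn[codes == g]), numeric(1))
  present <- grp_w > 0
  hi <- cumsum(grp_w)
  r_grp <- hi - grp_w / 2
  r <- r_grp[codes]

  structure(list(
    rank = r,
    variable = variable,
    groups = data.frame(value = labels[present], share = grp_w[present],
                        rank = r_grp[present], row.names = NULL)
  ), class = "fractional_rank")
}

#' @export
print.fractional_rank <- function(x, ...) {
  cat(sprintf("Weighted fractional ranks over '%s' (%d observations, %d tie groups)\n",
              x$variable, length(x$rank), nrow(x$groups)))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

rank_values <- function(ranks) {
  if (inherits(ranks, "fractional_rank")) ranks$rank else as.numeric(ranks)
}

#' Concentration index by the convenient covariance approach
#'
#' `CIX = (2 / mu) * cov_w(h, r)` where `mu` is the weighted mean of the
#' outcome, `r` the weighted fractional rank over the living-standards
#' ranking variable, and `cov_w` the weighted covariance with normalised
#' weights (population convention, under which the formula is exact). The
#' index lies in `[-1, 1]`; positive values mean the outcome is concentrated
#' among the better-off. For a binary outcome the attainable range is
#' `[mu - 1, 1 - mu]`.
#'
#' Inference uses the convenient-regression equivalence: the weighted least
#' squares slope of `2 * var_w(r) * h / mu` on `r` equals the index, and its
#' heteroskedasticity-robust (HC1) or, when `cluster` is given,
#' cluster-robust standard error is reported with a t reference
#' distribution (df = clusters - 1 when clustered, n - 2 otherwise).
#'
#' @param h numeric outcome vector (binary MDD indicator, or any
#'   non-negative outcome).
#' @param ranks a [weighted_fractional_rank()] result (or numeric ranks).
#' @param w strictly positive weights.
#' @param cluster optional primary-sampling-unit identifiers for
#'   cluster-robust standard errors.
#' @param ranking_variable optional name recorded on the estimate.
#' @return an object of class `cix_estimate`: list with `value`, `mu`, `se`,
#'   `p_value`, `n`, `ranking_variable`.
#' @examples
#' r <- weighted_fractional_rank(1:4, rep(1, 4))
#' concentration_index(c(0, 0, 1, 1), r, rep(1, 4))$value # 0.5 = 1 - mu
#' @export
concentration_index <- function(h, ranks, w, cluster = NULL, ranking_variable = NULL) {
  r <- rank_values(ranks)
  assert_positive_weights(w)
  assert_same_length(h, r, w, what = "`h`, ranks and `w`")
  if (anyNA(h)) stop("concentration_index: outcome has missing values", call. = FALSE)
  mu <- wmean(h, w)
  if (mu <= 0) stop("concentration_index: weighted mean of the outcome is zero; the index is undefined",
                    call. = FALSE)

  value <- 2 * wcov(h, r, w) / mu
  n <- length(h)
  s2r <- wvar(r, w)

  se <- NA_real_
  p <- NA_real_
  if (n >= 3L && s2r > 0) {
    ystar <- 2 * s2r * h / mu
    fit <- stats::lm(ystar ~ r, weights = w)
    # suppressWarnings: summary.lm complains on (near-)perfect fits, which are
    # legitimate degenerate inputs here (e.g. an outcome deterministic in rank)
    V <- suppressWarnings(if (!is.null(cluster)) {
      sandwich::vcovCL(fit, cluster = cluster)
    } else {
      sandwich::vcovHC(fit, type = "HC1")
    })
    se <- sqrt(V[2, 2])
    df <- if (!is.null(cluster)) length(unique(cluster)) - 1L else n - 2L
    if (se > 0 && df >= 1) p <- 2 * stats::pt(-abs(value / se), df = df)
  }

  structure(list(
    value = value, mu = mu, se = se, p_value = p, n = n,
    ranking_variable = ranking_variable %||%
      (if (inherits(ranks, "fractional_rank")) ranks$variable else NA_character_)
  ), class = "cix_estimate")
}

#' @export
print.cix_estimate <- function(x, ...) {
  cat(sprintf("Concentration index (ranked by %s): %.4f (se %.4f, p %s; mu = %.4f, n = %d)\n",
              x$ranking_variable, x$value, x$se, format.pval(x$p_value, digits = 3), x$mu, x$n))
  invisible(x)
}

#' Concentration curve
#'
#' Cumulative weighted outcome share against cumulative weighted population
#' share, ranked from lowest to highest living standard, anchored at (0, 0)
#' and (1, 1) with one interior point per tie group of the ranking variable.
#' A curve below the 45-degree diagonal means the outcome is concentrated
#' among the better-off. Twice the signed area between the diagonal and the
#' curve equals the concentration index exactly on grouped data.
#'
#' @inheritParams concentration_index
#' @param ranking_values ranking variable (see [weighted_fractional_rank()]).
#' @param order_levels optional declared category order.
#' @return object of class `concentration_curve`: list with `points`
#'   (`pop_share`, `outcome_share`), `below_diagonal`, `above_diagonal`
#'   (strict dominance flags) and `cix_from_area`.
#' @export
concentration_curve <- function(h, ranking_values, w, order_levels = NULL) {
  fr <- weighted_fractional_rank(ranking_values, w, order_levels = order_levels,
                                 variable = deparse(substitute(ranking_values))[1])
  if (anyNA(h)) stop("concentration_curve: outcome has missing values", call. = FALSE)
  mu <- wmean(h, w)
  if (mu <= 0) stop("concentration_curve: weighted mean of the outcome is zero", call. = FALSE)

  wn <- w / sum(w)
  # per tie group, in rank order
  ord <- order(fr$groups$rank)
  g <- match(fr$rank, fr$groups$rank)
  pop <- fr$groups$share[ord]
  out_share <- vapply(ord, function(k) sum(wn[g == k] * h[g == k]), numeric(1)) /
    sum(wn * h)
  p <- c(0, cumsum(pop))
  L <- c(0, cumsum(out_share))
  p[length(p)] <- 1
  L[length(L)] <- 1

  interior <- seq(2, length(p) - 1L)
  eps <- 1e-12
  below <- length(interior) > 0 && all(L[interior] <= p[interior] + eps) &&
    any(L[interior] < p[interior] - eps)
  above <- length(interior) > 0 && all(L[interior] >= p[interior] - eps) &&
    any(L[interior] > p[interior] + eps)

  # trapezoid area between diagonal and curve, times two
  dp <- diff(p)
  mid_gap <- (p[-1] + p[-length(p)]) / 2 - (L[-1] + L[-length(L)]) / 2
  cix_area <- 2 * sum(dp * mid_gap)

  structure(list(
    points = data.frame(pop_share = p, outcome_share = L),
    ranking_variable = fr$variable,
    below_diagonal = below, above_diagonal = above,
    cix_from_area = cix_area
  ), class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  pos <- if (x$below_diagonal) "below the line of equality (pro-rich)"
  else if (x$above_diagonal) "above the line of equality (pro-poor)"
  else "crossing or on the line of equality"
  cat(sprintf("Concentration curve over '%s': %d points, %s; 2 x area = %.4f\n",
              x$ranking_variable, nrow(x$points), pos, x$cix_from_area))
  invisible(x)
}

#' Concentration index within subgroups
#'
#' Recomputes fractional ranks within each subgroup (inequality is measured
#' relative to the subgroup's own living-standards distribution) and
#' returns one estimate per subgroup plus a comparator identifying the
#' largest and smallest index. Subgroups in which the outcome never occurs
#' have an undefined index and are flagged and excluded from the comparator.
#'
#' @param table cohort table.
#' @param outcome name of the binary outcome column.
#' @param ranking name of the ranking column (ordered factor or numeric).
#' @param subgroup name of the grouping column.
#' @param weight,cluster column names for weights and (optional) clusters.
#' @return data.frame with one row per subgroup (`subgroup`, `cix`, `se`,
#'   `p_value`, `mu`, `n`, `defined`); attributes `largest` and `smallest`
#'   name the comparator subgroups.
#' @export
subgroup_cix <- function(table, outcome, ranking, subgroup,
                         weight = "weight", cluster = "cluster_id") {
  x <- table[[subgroup]]
  if (!is.factor(x)) x <- factor(x)
  x <- droplevels(x)
  rows <- lapply(levels(x), function(lev) {
    i <- which(x == lev)
    h <- table[[outcome]][i]
    w <- table[[weight]][i]
    if (wmean(h, w) <= 0) {
      return(data.frame(subgroup = lev, cix = NA_real_, se = NA_real_,
                        p_value = NA_real_, mu = 0, n = length(i), defined = FALSE))
    }
    fr <- weighted_fractional_rank(table[[ranking]][i], w, variable = ranking)
    est <- concentration_index(h, fr, w,
                               cluster = if (!is.null(cluster) && cluster %in% names(table))
                                 table[[cluster]][i] else NULL,
                               ranking_variable = ranking)
    data.frame(subgroup = lev, cix = est$value, se = est$se,
               p_value = est$p_value, mu = est$mu, n = est$n, defined = TRUE)
  })
  out <- do.call(rbind, rows)
  ok <- out[out$defined, ]
  if (nrow(ok)) {
    attr(out, "largest") <- ok$subgroup[which.max(ok$cix)]
    attr(out, "smallest") <- ok$subgroup[which.min(ok$cix)]
  }
  out
}

#' Concentration index of each food-group component
#'
#' One concentration index per food-group flag against the given ranking
#' variable, with a sign/significance label. Groups never consumed have an
#' undefined index and are flagged; groups consumed by everyone have index
#' 0 (a constant indicator carries no inequality).
#'
#' @inheritParams subgroup_cix
#' @param alpha significance level for the labels.
#' @return data.frame with one row per food group: `food_group`, `cix`,
#'   `se`, `p_value`, `mu`, `defined`, `label`.
#' @export
component_cix <- function(table, ranking, weight = "weight",
                          cluster = "cluster_id", alpha = 0.05) {
  w <- table[[weight]]
  fr <- weighted_fractional_rank(table[[ranking]], w, variable = ranking)
  cl <- if (!is.null(cluster) && cluster %in% names(table)) table[[cluster]] else NULL
  rows <- lapply(food_group_columns(), function(cc) {
    h <- table[[cc]]
    if (anyNA(h)) stop("component_cix: food-group flags contain missing values", call. = FALSE)
    if (wmean(h, w) <= 0) {
      return(data.frame(food_group = sub("^fg_", "", cc), cix = NA_real_,
                        se = NA_real_, p_value = NA_real_, mu = 0,
                        defined = FALSE, label = "undefined (never consumed)"))
    }
    est <- concentration_index(h, fr, w, cluster = cl, ranking_variable = ranking)
    lab <- if (!is.finite(est$p_value) || est$p_value >= alpha) {
      "not significant"
    } else if (est$value > 0) "concentrated among better-off"
    else "concentrated among worse-off"
    data.frame(food_group = sub("^fg_", "", cc), cix = est$value, se = est$se,
               p_value = est$p_value, mu = est$mu, defined = TRUE, label = lab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
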