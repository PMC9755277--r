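#' Asset-based wealth index by weighted principal components
#'
#' Reproduces the DHS wealth-index construction: asset indicators are
#' standardised to weighted mean 0 / variance 1, the first principal axis of
#' the weighted correlation structure is extracted, and each household's
#' score is its projection on that axis. The sign of the axis is arbitrary,
#' so it is anchored: the score is flipped, if needed, to correlate
#' positively with a declared affluence indicator. Scores are then cut into
#' weighted quintiles (boundary convention: a household exactly on a
#' boundary goes to the lower quintile).
#'
#' @param assets data.frame or matrix of numeric asset indicators, one row
#'   per household, at least two columns with nonzero variance. Constant
#'   columns are dropped with a warning.
#' @param weights strictly positive household weights.
#' @param anchor name of the indicator column whose weighted correlation
#'   with the score must be positive (the "affluence anchor").
#' @return an object of class `wealth_score`: a list with `score`,
#'   `quintile` (integer 1 = poorest ... 5 = richest), `quintile_label`,
#'   `loadings`, `dropped` (names of dropped constant columns), and
#'   `explained_share` (share of total standardised variance carried by the
#'   first axis).
#' @examples
#' a <- data.frame(x = c(0, 0, 1, 1, 2, 2), y = c(0, 1, 1, 2, 2, 3),
#'                 z = c(1, 0, 1, 0, 2, 2))
#' ws <- compute_wealth_scores(a, weights = rep(1, 6), anchor = "x")
#' ws$quintile
#' @export
compute_wealth_scores <- function(assets, weights, anchor) {
  X <- as.matrix(as.data.frame(assets))
  if (!is.numeric(X)) stop("compute_wealth_scores: asset indicators must be numeric", call. = FALSE)
  if (anyNA(X)) stop("compute_wealth_scores: asset indicators contain missing values", call. = FALSE)
  assert_positive_weights(weights)
  if (nrow(X) != length(weights)) {
    stop("compute_wealth_scores: one weight per household is required", call. = FALSE)
  }
  if (!anchor %in% colnames(X)) {
    stop(sprintf("compute_wealth_scores: anchor column '%s' not found", anchor), call. = FALSE)
  }

  wn <- weights / sum(weights)
  v <- apply(X, 2, wvar, w = weights)
  dropped <- colnames(X)[v <= .Machine$double.eps * 100]
  if (length(dropped)) {
    warning("compute_wealth_scores: dropping constant indicator(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
    v <- v[setdiff(names(v), dropped)]
  }
  if (ncol(X) < 2L) {
    stop("compute_wealth_scores: need at least two non-constant indicators", call. = FALSE)
  }
  if (!anchor %in% colnames(X)) {
    stop("compute_wealth_scores: the anchor column is constant and was dropped", call. = FALSE)
  }

  mu <- colSums(wn * X)
  Z <- sweep(sweep(X, 2, mu), 2, sqrt(v), `/`)
  # weighted correlation matrix of the standardised indicators
  R <- crossprod(Z * sqrt(wn), Z * sqrt(wn))
  ev <- eigen(R, symmetric = TRUE)
  axis <- ev$vectors[, 1]
  score <- drop(Z %*% axis)
  if (wcov(score, X[, anchor], weights) < 0) {
    axis <- -axis
    score <- -score
  }

  if (length(unique(score)) < 5L) {
    stop("compute_wealth_scores: fewer than 5 distinct scores; quintiles are undefined",
         call. = FALSE)
  }
  q <- weighted_quantile_groups(score, weights, 5L)

  structure(list(
    score = score,
    quintile = q,
    quintile_label = factor(WEALTH_LEVELS[q], WEALTH_LEVELS, ordered = TRUE),
    loadings = stats::setNames(axis, colnames(X)),
    dropped = dropped,
    explained_share = ev$values[1] / sum(ev$values)
  ), class = "wealth_score")
}

#' @export
print.wealth_score <- function(x, ...) {
  cat(sprintf("Wealth index: %d households, first axis carries %.1f%% of variance\n",
              length(x$score), 100 * x$explained_share))
  cat("Loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}
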