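`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(1, pmax(0, x))

#' Weighted mean with positive weights
#' @param x numeric vector.
#' @param w positive weights, same length as `x`.
#' @return scalar weighted mean.
#' @keywords internal
wmean <- function(x, w) {
  sum(w * x) / sum(w)
}

#' Population-style weighted covariance
#'
#' Weights are normalised to sum to one and no small-sample (n-1) correction
#' is applied: under this convention the convenient covariance formula for
#' the concentration index is exact.
#' @keywords internal
wcov <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  sum(w * (x - mx) * (y - my))
}

wvar <- function(x, w) wcov(x, x, w)

assert_positive_weights <- function(w, what = "weights") {
  if (anyNA(w) || !is.numeric(w) || any(!is.finite(w)) || any(w <= 0)) {
    stop(sprintf("`%s` must be finite, strictly positive and free of missing values", what),
         call. = FALSE)
  }
  invisible(w)
}

assert_same_length <- function(..., what = NULL) {
  lens <- lengths(list(...))
  if (length(unique(lens)) != 1L) {
    stop(sprintf("length mismatch between %s", what %||% "input vectors"), call. = FALSE)
  }
}

#' Cut a continuous score into weighted fifths
#'
#' Tie groups share the midpoint of their weighted CDF interval, so tied
#' scores always land in the same group; a midpoint falling exactly on a
#' boundary is assigned to the lower group. Each group's weighted share is
#' 1/n_groups up to one observation's weight.
#'
#' @param score numeric vector to rank on.
#' @param w strictly positive weights.
#' @param n_groups number of groups (5 for wealth quintiles).
#' @return integer vector of group codes in `1:n_groups` (1 = lowest score).
#' @keywords internal
weighted_quantile_groups <- function(score, w, n_groups = 5L) {
  assert_positive_weights(w)
  assert_same_length(score, w, what = "`score` and `w`")
  if (anyNA(score) || any(!is.finite(score))) {
    stop("`score` must be finite and non-missing", call. = FALSE)
  }
  wn <- w / sum(w)
  u <- sort(unique(score))
  g <- match(score, u)
  grp_w <- vapply(split(wn, g), sum, numeric(1))
  hi <- cumsum(grp_w)
  lo <- hi - grp_w
  mid <- (lo + hi) / 2
  breaks <- seq_len(n_groups - 1L) / n_groups
  gq <- findInterval(mid, breaks, left.open = TRUE) + 1L
  gq[g]
}

# Canonical categorical codings shared by the generator, the recodes and the
# regression design. Food-group order follows the 8-group IYCF definition.
FOOD_GROUPS <- c("breastfeeding", "grains", "legumes", "dairy",
                 "flesh", "eggs", "vita_fruit_veg", "other_fruit_veg")
WEALTH_LEVELS <- c("poorest", "poorer", "middle", "richer", "richest")
EDU_LEVELS <- c("none", "primary", "secondary", "higher")
AGE_BANDS <- c("6-12", "13-18", "19-23")
ANC_LEVELS <- c("<4", ">=4")
LIVING_LEVELS <- c("1", "2", "3+")
MOTHER_AGE_LEVELS <- c("15-19", "20-24", "25-29", "30-49")
DIVISIONS <- c("barisal", "chittagong", "dhaka", "khulna",
               "mymensingh", "rajshahi", "rangpur", "sylhet")
RESIDENCE_LEVELS <- c("rural", "urban")
YESNO <- c("no", "yes")
SEX_LEVELS <- c("male", "female")

#' Column names of the eight food-group indicators
#' @return character vector of the `fg_*` column names in survey tables.
#' @export
food_group_columns <- function() paste0("fg_", FOOD_GROUPS)

#' Canonical factor levels for survey covariates
#' @return named list mapping covariate column names to their level sets
#'   (first level = conventional reference category).
#' @export
covariate_levels <- function() {
  list(
    wealth_quintile = WEALTH_LEVELS,
    mother_education = EDU_LEVELS,
    partner_education = EDU_LEVELS,
    mother_age_group = MOTHER_AGE_LEVELS,
    residence = RESIDENCE_LEVELS,
    media_exposure = YESNO,
    currently_working = YESNO,
    postnatal_visited = YESNO,
    anc_category = ANC_LEVELS,
    child_sex = SEX_LEVELS,
    living_children_category = LIVING_LEVELS,
    child_age_band = AGE_BANDS,
    division = DIVISIONS
  )
}

#' Covariates entering the decomposition regression
#'
#' The default linear-probability-model design: every socio-demographic
#' covariate of the child recode except the child's age band (which is used
#' for subgroup analyses, not in the decomposition).
#' @return character vector of column names.
#' @export
mdd_model_covariates <- function() {
  c("mother_age_group", "mother_education", "wealth_quintile",
    "partner_education", "residence", "media_exposure", "currently_working",
    "postnatal_visited", "anc_category", "child_sex",
    "living_children_category", "division")
}

#' Default reference categories for the decomposition regression
#' @return named list, one reference level per modelled covariate.
#' @export
mdd_reference_levels <- function() {
  list(
    mother_age_group = "15-19", mother_education = "none",
    wealth_quintile = "poorest", partner_education = "none",
    residence = "rural", media_exposure = "no", currently_working = "no",
    postnatal_visited = "no", anc_category = "<4", child_sex = "male",
    living_children_category = "1", division = "barisal"
  )
}
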