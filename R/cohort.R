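#' Recode raw survey fields into analysis covariates
#'
#' Applies the standard child-recode derivations: `media_exposure` is
#' `"yes"` when any of newspaper/TV/radio is used at least weekly;
#' `anc_category` dichotomises the ANC visit count at 4 (4 visits fall in
#' the upper class); `living_children_category` groups parity into
#' 1 / 2 / 3+; `child_age_band` bands age in months into 6--12, 13--18,
#' 19--23 (other ages become `NA`). Unknown raw codes (negative counts, DHS
#' "don't know" codes 98/99) are reported via a message and treated as
#' missing.
#'
#' @param table survey table with raw fields `newspaper_weekly`,
#'   `tv_weekly`, `radio_weekly`, `anc_visits`, `living_children`,
#'   `child_age_months`.
#' @return the table with the four derived factor columns appended.
#' @export
recode_covariates <- function(table) {
  need <- c("newspaper_weekly", "tv_weekly", "radio_weekly",
            "anc_visits", "living_children", "child_age_months")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("recode_covariates: missing raw fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  unknown <- 0L
  clean_binary <- function(x) {
    bad <- !is.na(x) & !(x %in% c(0, 1))
    unknown <<- unknown + sum(bad)
    x[bad] <- NA
    x
  }
  clean_count <- function(x) {
    bad <- !is.na(x) & (x < 0 | x >= 90)   # 98/99 = don't know / missing codes
    unknown <<- unknown + sum(bad)
    x[bad] <- NA
    x
  }

  np <- clean_binary(table$newspaper_weekly)
  tv <- clean_binary(table$tv_weekly)
  rd <- clean_binary(table$radio_weekly)
  anc <- clean_count(table$anc_visits)
  liv <- clean_count(table$living_children)

  # any weekly source => exposed, even if another source is unrecorded;
  # all-zero => unexposed; otherwise undetermined
  any1 <- (np %in% 1) | (tv %in% 1) | (rd %in% 1)
  all0 <- !is.na(np) & !is.na(tv) & !is.na(rd) & np == 0 & tv == 0 & rd == 0
  media <- ifelse(any1, "yes", ifelse(all0, "no", NA))

  anc_cat <- ifelse(is.na(anc), NA, ifelse(anc >= 4, ">=4", "<4"))
  liv_cat <- ifelse(is.na(liv) | liv < 1, NA,
                    ifelse(liv >= 3, "3+", as.character(liv)))
  band <- AGE_BANDS[age_band_index(table$child_age_months)]

  if (unknown > 0) {
    message(sprintf("recode_covariates: %d unknown raw code(s) treated as missing", unknown))
  }

  table$media_exposure <- factor(media, YESNO)
  table$anc_category <- factor(anc_cat, ANC_LEVELS)
  table$living_children_category <- factor(liv_cat, LIVING_LEVELS)
  table$child_age_band <- factor(band, AGE_BANDS)
  table
}

#' Apply the cohort filter cascade
#'
#' Three ordered stages reproduce the analysis cohort construction:
#' \enumerate{
#'   \item keep children aged 6--23 months inclusive;
#'   \item drop rows with a missing value on any of the 8 food-group flags;
#'   \item drop rows with a missing value on any modelled covariate.
#' }
#'
#' @param table survey table (recoded, see [recode_covariates()]).
#' @param covariates covariate columns checked at stage 3; defaults to the
#'   decomposition design of [mdd_model_covariates()].
#' @return a list with `table` (the filtered cohort) and `report`, a
#'   `filter_cascade_report` data.frame with one row per stage
#'   (`stage`, `rows_in`, `rows_dropped`, `rows_out`) plus attributes
#'   `final_n` (unweighted) and `final_weighted_n`.
#' @export
apply_filter_cascade <- function(table, covariates = mdd_model_covariates()) {
  miss <- setdiff(c("child_age_months", "weight", food_group_columns(), covariates),
                  names(table))
  if (length(miss)) {
    stop("apply_filter_cascade: table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  stages <- list()
  run_stage <- function(tab, name, keep) {
    out <- tab[keep, , drop = FALSE]
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, rows_in = nrow(tab),
      rows_dropped = nrow(tab) - nrow(out), rows_out = nrow(out))
    if (nrow(out) == 0L) {
      stop(sprintf("apply_filter_cascade: no children remain after stage '%s'", name),
           call. = FALSE)
    }
    out
  }

  tab <- run_stage(table, "age_6_23_months",
                   !is.na(table$child_age_months) &
                     table$child_age_months >= 6 & table$child_age_months <= 23)
  fg <- as.matrix(tab[food_group_columns()])
  tab <- run_stage(tab, "complete_food_groups", stats::complete.cases(fg))
  tab <- run_stage(tab, "complete_covariates",
                   stats::complete.cases(tab[covariates]))

  report <- do.call(rbind, stages)
  class(report) <- c("filter_cascade_report", "data.frame")
  attr(report, "final_n") <- nrow(tab)
  attr(report, "final_weighted_n") <- sum(tab$weight)
  list(table = tab, report = report)
}

#' @export
print.filter_cascade_report <- function(x, ...) {
  cat("Filter cascade:\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("Final cohort: %d children (weighted n = %.1f)\n",
              attr(x, "final_n"), attr(x, "final_weighted_n")))
  invisible(x)
}

#' Minimum dietary diversity from the eight food-group flags
#'
#' Counts the distinct food groups consumed and marks MDD when the count
#' reaches at least 5 of 8. All eight flags must be non-missing: run
#' [apply_filter_cascade()] first.
#'
#' @param food_groups an n x 8 matrix or data.frame of 0/1 flags (any column
#'   order; a full survey table is accepted and subset to
#'   [food_group_columns()]).
#' @return a data.frame with integer `n_groups` (0--8) and binary `mdd`.
#' @examples
#' compute_mdd(rbind(c(1, 1, 1, 1, 1, 0, 0, 0))) # 5 groups -> mdd = 1
#' @export
compute_mdd <- function(food_groups) {
  if (is.data.frame(food_groups) && all(food_group_columns() %in% names(food_groups))) {
    food_groups <- food_groups[food_group_columns()]
  }
  fg <- as.matrix(food_groups)
  if (ncol(fg) != 8L) {
    stop("compute_mdd: expected 8 food-group columns, got ", ncol(fg), call. = FALSE)
  }
  if (anyNA(fg)) {
    stop("compute_mdd: food-group flags contain missing values; apply the filter cascade first",
         call. = FALSE)
  }
  if (!all(fg %in% c(0, 1))) {
    stop("compute_mdd: food-group flags must be 0/1", call. = FALSE)
  }
  cnt <- as.integer(rowSums(fg))
  data.frame(n_groups = cnt, mdd = as.integer(cnt >= 5L))
}

#' Survey-weighted descriptive table
#'
#' Table-1-style summary: per category of each variable the weighted count,
#' the weighted column percentage, and the weighted MDD prevalence; plus an
#' overall prevalence row. Percentages within a variable sum to 100 before
#' rounding.
#'
#' @param table filtered, recoded cohort.
#' @param mdd binary outcome vector (or the `mdd` column of
#'   [compute_mdd()]'s result), aligned with `table` rows.
#' @param variables covariate columns to tabulate.
#' @param weight name of the weight column.
#' @return a data.frame with columns `variable`, `category`, `weighted_n`,
#'   `pct`, `mdd_pct`; the first row (`variable == "overall"`) carries the
#'   overall weighted prevalence.
#' @export
weighted_descriptives <- function(table, mdd,
                                  variables = c(intersect(
                                    c("child_age_band", mdd_model_covariates()),
                                    names(table))),
                                  weight = "weight") {
  if (is.data.frame(mdd)) mdd <- mdd$mdd
  w <- table[[weight]]
  assert_positive_weights(w)
  assert_same_length(mdd, w, what = "`mdd` and table rows")

  rows <- list(data.frame(variable = "overall", category = "",
                          weighted_n = sum(w), pct = 100,
                          mdd_pct = 100 * wmean(mdd, w)))
  for (v in variables) {
    x <- table[[v]]
    if (!is.factor(x)) x <- factor(x)
    cats <- levels(x)
    wn <- vapply(cats, function(cc) sum(w[x == cc]), numeric(1))
    mp <- vapply(cats, function(cc) {
      i <- which(x == cc)
      if (length(i)) 100 * wmean(mdd[i], w[i]) else 0
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, category = cats, weighted_n = wn,
      pct = 100 * wn / sum(w), mdd_pct = mp, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
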