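#' Weighted linear probability model for the decomposition
#'
#' Weighted least squares of the binary outcome on a treatment-coded dummy
#' design built from categorical covariates with declared reference
#' categories. The linear identity `fitted + residual = observed` holds
#' exactly, which is what makes the decomposition of the concentration
#' index exact.
#'
#' @param table cohort table (filtered and recoded).
#' @param outcome name of the binary outcome column, or a numeric vector.
#' @param covariates covariate column names entering the design.
#' @param weight name of the weight column.
#' @param references named list of reference categories (defaults to
#'   [mdd_reference_levels()] for known covariates, first level otherwise).
#' @param weighted set `FALSE` to fit unweighted (weights only used for the
#'   means); default fits survey-weighted.
#' @return object of class `lpm_fit`: list with `alpha`, `beta` (named
#'   coefficients), `xbar` (weighted dummy means), `residuals`, `mu`,
#'   `design` (data.frame dummy/variable/category/reference), `X` (the
#'   dummy matrix), `n`.
#' @export
fit_lpm <- function(table, outcome, covariates = mdd_model_covariates(),
                    weight = "weight", references = mdd_reference_levels(),
                    weighted = TRUE) {
  y <- if (is.character(outcome) && length(outcome) == 1L) table[[outcome]] else outcome
  w <- table[[weight]]
  assert_positive_weights(w)
  assert_same_length(y, w, what = "outcome and weights")
  if (anyNA(y)) stop("fit_lpm: outcome has missing values", call. = FALSE)
  mu <- wmean(y, w)
  if (mu <= 0) stop("fit_lpm: weighted outcome mean is zero", call. = FALSE)
  miss <- setdiff(covariates, names(table))
  if (length(miss)) stop("fit_lpm: missing covariate column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)

  df <- table[covariates]
  design_rows <- list()
  for (v in covariates) {
    x <- df[[v]]
    if (anyNA(x)) stop(sprintf("fit_lpm: covariate '%s' has missing values", v), call. = FALSE)
    x <- factor(as.character(x),
                levels = if (is.factor(df[[v]])) levels(df[[v]]) else sort(unique(as.character(x))))
    x <- droplevels(x)
    ref <- references[[v]]
    if (!is.null(ref) && ref %in% levels(x)) x <- stats::relevel(x, ref)
    df[[v]] <- x
    if (nlevels(x) < 2L) {
      stop(sprintf("fit_lpm: covariate '%s' has a single observed category", v), call. = FALSE)
    }
    design_rows[[v]] <- data.frame(
      dummy = paste0(v, levels(x)[-1]), variable = v,
      category = levels(x)[-1], reference = levels(x)[1])
  }
  design <- do.call(rbind, design_rows)
  rownames(design) <- NULL

  mm <- stats::model.matrix(~ ., data = df)
  fit <- stats::lm.wfit(mm, y, if (weighted) w else rep(1, length(y)))
  if (any(is.na(fit$coefficients))) {
    stop("fit_lpm: collinear design; aliased dummies: ",
         paste(names(fit$coefficients)[is.na(fit$coefficients)], collapse = ", "),
         call. = FALSE)
  }

  X <- mm[, -1, drop = FALSE]
  wn <- w / sum(w)
  xbar <- colSums(wn * X)
  res <- y - drop(mm %*% fit$coefficients)

  structure(list(
    alpha = unname(fit$coefficients[1]),
    beta = fit$coefficients[-1],
    xbar = xbar,
    residuals = res,
    mu = mu,
    design = design,
    X = X,
    n = length(y),
    weighted = weighted
  ), class = "lpm_fit")
}

#' @export
print.lpm_fit <- function(x, ...) {
  cat(sprintf("Linear probability model: %d observations, %d dummies, mu = %.4f\n",
              x$n, length(x$beta), x$mu))
  invisible(x)
}

#' Decompose a concentration index into covariate contributions
#'
#' Regression-based decomposition: with the linear model
#' `y = alpha + sum_k beta_k X_k + eps`, the concentration index of `y`
#' splits as `CIX = sum_k (beta_k * Xbar_k / mu) * C_k + GC_eps / mu`, where
#' `C_k = (2 / Xbar_k) * cov_w(X_k, r)` is the concentration index of dummy
#' `k` over the *same* fractional ranks `r` as the overall index, the
#' factor `beta_k * Xbar_k / mu` is the elasticity of the outcome with
#' respect to `X_k`, and the generalized concentration index of the
#' residuals `GC_eps = 2 * cov_w(eps, r)` carries the unexplained part.
#' The identity `explained + residual = overall` is enforced to 1e-10 (the
#' residual is computed both directly from `eps` and as
#' `overall - explained`; a discrepancy raises an internal-consistency
#' error).
#'
#' @param fit an [fit_lpm()] result.
#' @param ranks fractional ranks consistent with the fit's rows.
#' @param w weights consistent with the fit's rows.
#' @param overall the overall [concentration_index()] estimate of the
#'   outcome over the same ranks (or a bare numeric value).
#' @return object of class `decomposition_table`: list with `rows`
#'   (per-category elasticity, `c_k`, contribution, `pct_contribution`),
#'   `variable_totals`, `explained`, `residual`, `overall`, `mu`,
#'   `ranking_variable`.
#' @export
decompose_cix <- function(fit, ranks, w, overall) {
  if (!inherits(fit, "lpm_fit")) stop("decompose_cix: `fit` must come from fit_lpm()", call. = FALSE)
  r <- rank_values(ranks)
  assert_same_length(r, fit$residuals, w, what = "ranks, fit rows and weights")
  overall_value <- if (inherits(overall, "cix_estimate")) overall$value else as.numeric(overall)

  keep <- fit$xbar > 0
  if (any(!keep)) {
    warning("decompose_cix: dummies with zero weighted mean excluded: ",
            paste(names(fit$xbar)[!keep], collapse = ", "), call. = FALSE)
  }
  X <- fit$X[, keep, drop = FALSE]
  beta <- fit$beta[keep]
  xbar <- fit$xbar[keep]
  design <- fit$design[keep, , drop = FALSE]

  ck <- vapply(seq_len(ncol(X)), function(k) 2 * wcov(X[, k], r, w) / xbar[k], numeric(1))
  elasticity <- beta * xbar / fit$mu
  contribution <- elasticity * ck

  explained <- sum(contribution)
  residual_direct <- 2 * wcov(fit$residuals, r, w) / fit$mu
  residual_identity <- overall_value - explained
  if (abs(residual_direct - residual_identity) > 1e-8) {
    stop(sprintf(paste("decompose_cix: internal inconsistency; residual from eps (%.3e)",
                       "and overall - explained (%.3e) disagree. Are ranks, weights and",
                       "overall taken from the same cohort as the fit?"),
                 residual_direct, residual_identity), call. = FALSE)
  }

  rows <- data.frame(
    variable = design$variable, category = design$category,
    reference = design$reference,
    elasticity = unname(elasticity), c_k = ck,
    contribution = unname(contribution),
    pct_contribution = NA_real_, row.names = NULL)

  vt <- stats::aggregate(contribution ~ variable, data = rows, FUN = sum)
  vt <- vt[match(unique(rows$variable), vt$variable), ]
  vt$pct_contribution <- NA_real_
  rownames(vt) <- NULL

  out <- structure(list(
    rows = rows, variable_totals = vt,
    explained = explained, residual = residual_direct,
    overall = overall_value, mu = fit$mu,
    ranking_variable = if (inherits(ranks, "fractional_rank")) ranks$variable else NA_character_
  ), class = "decomposition_table")
  percentage_contributions(out)
}

#' Finalise percentage contributions of a decomposition table
#'
#' `pct = contribution / overall * 100` for every category row, every
#' per-variable total, and the explained/residual split; negative
#' percentages indicate a factor that reduces the observed concentration.
#'
#' @param table a `decomposition_table`.
#' @return the table with percentage columns filled;
#'   `pct_explained + pct_residual = 100` to 1e-8.
#' @export
percentage_contributions <- function(table) {
  if (!inherits(table, "decomposition_table")) {
    stop("percentage_contributions: expected a decomposition_table", call. = FALSE)
  }
  if (table$overall == 0) {
    stop("percentage_contributions: overall concentration index is zero; percentages are undefined",
         call. = FALSE)
  }
  table$rows$pct_contribution <- 100 * table$rows$contribution / table$overall
  table$variable_totals$pct_contribution <-
    100 * table$variable_totals$contribution / table$overall
  table$pct_explained <- 100 * table$explained / table$overall
  table$pct_residual <- 100 * table$residual / table$overall
  table
}

#' @export
print.decomposition_table <- function(x, digits = 4, ...) {
  cat(sprintf("Decomposition of CIX = %.4f (ranked by %s), mu = %.4f\n",
              x$overall, x$ranking_variable, x$mu))
  rows <- x$rows
  rows$elasticity <- round(rows$elasticity, digits)
  rows$c_k <- round(rows$c_k, digits)
  rows$contribution <- round(rows$contribution, digits)
  rows$pct_contribution <- round(rows$pct_contribution, 2)
  print(rows[, c("variable", "category", "elasticity", "c_k",
                 "contribution", "pct_contribution")], row.names = FALSE)
  cat(sprintf("Explained %.5f (%.2f%%), residual %.5f (%.2f%%)\n",
              x$explained, x$pct_explained, x$residual, x$pct_residual))
  invisible(x)
}

#' Export a decomposition table as a flat data.frame
#'
#' Rounds to report precision (elasticity, component index and contribution
#' to 4 decimals; percentages to 2) and appends per-variable totals and the
#' explained/residual split, matching the layout of published decomposition
#' tables.
#'
#' @param x a `decomposition_table`.
#' @return a data.frame ready for `write.csv`.
#' @export
format_decomposition <- function(x) {
  rows <- x$rows
  out <- data.frame(
    variable = rows$variable, category = rows$category, row_type = "category",
    elasticity = round(rows$elasticity, 4), c_k = round(rows$c_k, 4),
    contribution = round(rows$contribution, 4),
    pct_contribution = round(rows$pct_contribution, 2))
  vt <- x$variable_totals
  multi <- vt$variable[vt$variable %in% rows$variable[duplicated(rows$variable)]]
  tot <- data.frame(
    variable = vt$variable[vt$variable %in% multi], category = "total",
    row_type = "total", elasticity = NA, c_k = NA,
    contribution = round(vt$contribution[vt$variable %in% multi], 4),
    pct_contribution = round(vt$pct_contribution[vt$variable %in% multi], 2))
  foot <- data.frame(
    variable = c("explained", "residual", "overall"), category = "",
    row_type = c("explained", "residual", "overall"),
    elasticity = NA, c_k = NA,
    contribution = round(c(x$explained, x$residual, x$overall), 5),
    pct_contribution = c(round(x$pct_explained, 2), round(x$pct_residual, 2), 100))
  out <- rbind(out, tot, foot)
  out[order(match(out$variable, c(unique(rows$variable), "explained", "residual", "overall")),
            out$row_type == "total"), ]
}

# ---- verification of published decomposition tables ------------------------

decimal_places <- function(s) {
  s <- sub("^\\s*-?", "", s)
  ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0L)
}

half_ulp <- function(s) 0.5 * 10^(-decimal_places(s))

#' Read a transcribed published decomposition table
#'
#' The fixture keeps every printed number as a string so that its printed
#' precision (number of decimals) is available to the verifier.
#'
#' @param path CSV with columns `variable`, `category`, `row_type`
#'   (`category`/`total`/`explained`/`residual`/`overall`), `elasticity`,
#'   `c_k`, `contribution`, `pct`.
#' @return data.frame of character columns.
#' @export
read_published_decomposition <- function(path) {
  utils::read.csv(path, colClasses = "character")
}

#' Verify the internal arithmetic of a published decomposition table
#'
#' Recomputes, from the printed numbers alone, every arithmetic relation a
#' decomposition table must satisfy: per category-row
#' `contribution = elasticity x C_k` and
#' `pct = elasticity x C_k / overall x 100`; per variable total the sum of
#' its printed category contributions and percentages; and the
#' explained/residual split against the sum of all category rows. Each
#' check carries a tolerance that propagates the rounding half-ulp of every
#' printed input through the recomputation, so a flag means the printed
#' numbers cannot be reconciled at their own precision. Disagreements are
#' findings about the published table, not failures of the verifier.
#'
#' @param published a table from [read_published_decomposition()] (must
#'   contain one `overall` row).
#' @return data.frame report: one row per check with `variable`,
#'   `category`, `check`, `printed`, `recomputed`, `tolerance`, `agree`.
#' @export
verify_published_table <- function(published) {
  stopifnot(all(c("variable", "category", "row_type", "elasticity",
                  "c_k", "contribution", "pct") %in% names(published)))
  ov_row <- published[published$row_type == "overall", ]
  if (nrow(ov_row) != 1L) stop("verify_published_table: need exactly one 'overall' row", call. = FALSE)
  overall <- as.numeric(ov_row$contribution)
  ulp_ov <- half_ulp(ov_row$contribution)

  cat_rows <- published[published$row_type == "category", ]
  checks <- list()
  add <- function(variable, category, check, printed, recomputed, tolerance) {
    checks[[length(checks) + 1L]] <<- data.frame(
      variable = variable, category = category, check = check,
      printed = printed, recomputed = recomputed, tolerance = tolerance,
      agree = is.finite(recomputed) && abs(recomputed - printed) <= tolerance)
  }

  for (i in seq_len(nrow(cat_rows))) {
    rw <- cat_rows[i, ]
    el <- as.numeric(rw$elasticity); ck <- as.numeric(rw$c_k)
    ctr <- as.numeric(rw$contribution); pct <- as.numeric(rw$pct)
    prod <- el * ck
    # rounding slack of the printed inputs propagated through the product
    slack <- half_ulp(rw$elasticity) * abs(ck) + half_ulp(rw$c_k) * abs(el)
    add(rw$variable, rw$category, "contribution = elasticity x C_k",
        ctr, prod, slack + half_ulp(rw$contribution))
    pct_tol <- 100 * slack / abs(overall) +
      100 * abs(prod) * ulp_ov / overall^2 + half_ulp(rw$pct)
    add(rw$variable, rw$category, "pct = contribution / overall x 100",
        pct, 100 * prod / overall, pct_tol)
  }

  tot_rows <- published[published$row_type == "total", ]
  for (i in seq_len(nrow(tot_rows))) {
    rw <- tot_rows[i, ]
    part <- cat_rows[cat_rows$variable == rw$variable, ]
    add(rw$variable, "total", "total contribution = sum of category rows",
        as.numeric(rw$contribution), sum(as.numeric(part$contribution)),
        sum(half_ulp(part$contribution)) + half_ulp(rw$contribution))
    add(rw$variable, "total", "total pct = sum of category rows",
        as.numeric(rw$pct), sum(as.numeric(part$pct)),
        sum(half_ulp(part$pct)) + half_ulp(rw$pct))
  }

  expl_sum <- sum(as.numeric(cat_rows$contribution))
  expl_tol <- sum(half_ulp(cat_rows$contribution))
  ex_row <- published[published$row_type == "explained", ]
  if (nrow(ex_row) == 1L) {
    add("explained", "", "explained = sum of all contributions",
        as.numeric(ex_row$contribution), expl_sum,
        expl_tol + half_ulp(ex_row$contribution))
    add("explained", "", "pct explained = explained / overall x 100",
        as.numeric(ex_row$pct), 100 * expl_sum / overall,
        100 * expl_tol / abs(overall) + 100 * abs(expl_sum) * ulp_ov / overall^2 +
          half_ulp(ex_row$pct))
  }
  rs_row <- published[published$row_type == "residual", ]
  if (nrow(rs_row) == 1L) {
    add("residual", "", "residual = overall - explained",
        as.numeric(rs_row$contribution), overall - expl_sum,
        expl_tol + ulp_ov + half_ulp(rs_row$contribution))
    add("residual", "", "pct residual = 100 - pct explained",
        as.numeric(rs_row$pct), 100 * (overall - expl_sum) / overall,
        100 * expl_tol / abs(overall) + 100 * abs(expl_sum) * ulp_ov / overall^2 +
          half_ulp(rs_row$pct))
  }

  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  attr(out, "overall") <- overall
  attr(out, "n_flagged") <- sum(!out$agree)
  out
}
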