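new_fit_result <- function(terms, model_kind, n_used) {
  structure(list(terms = terms, model_kind = model_kind,
                 n_used = as.integer(n_used)), class = "screening_fit")
}

#' @export
print.screening_fit <- function(x, ...) {
  cat("Fit (", x$model_kind, "), complete cases n = ", x$n_used, "\n", sep = "")
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}

complete_case_frame <- function(cohort, outcome, items) {
  cols <- c(outcome, items)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("column(s) not in cohort: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(cohort)[cols]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df
}

#' Standardized linear regression of a binary outcome on binary items
#'
#' Ordinary least squares of the 0/1 outcome on the 0/1 risk indicators
#' after scaling the modelled columns to unit variance (the outcome too, by
#' default). The returned standardized partial regression coefficients
#' (SPRCs) are the basis of the coefficient-times-100 item scores. Records
#' with any missing value among the modelled columns are dropped (listwise
#' deletion) and the complete-case count is reported.
#'
#' @param cohort a `cohort` or data frame.
#' @param outcome name of the binary outcome column (both classes required).
#' @param items character vector of indicator column names.
#' @param standardize_outcome also scale the outcome (default `TRUE`); with
#'   `FALSE` coefficients are in outcome units per predictor SD.
#' @return a `screening_fit` with per-term `sprc`, plus VIFs.
#' @examples
#' coh <- generate_cohort(simulation_params("first_visit", 400, seed = 3))
#' fit <- fit_linear_standardized(coh, "admin_cooperation",
#'                                c("maternal_age_lt25", "partner_status"))
#' fit$terms$sprc
#' @export
fit_linear_standardized <- function(cohort, outcome, items,
                                    standardize_outcome = TRUE) {
  df <- complete_case_frame(cohort, outcome, items)
  if (nrow(df) < length(items) + 2)
    stop("too few complete cases for a standardized fit", call. = FALSE)
  y <- df[[outcome]]
  if (length(unique(y)) < 2)
    stop("outcome has a single class in the complete cases", call. = FALSE)
  X <- as.matrix(df[items])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance item(s): ",
         paste(items[sds == 0], collapse = ", "), call. = FALSE)
  Xs <- scale(X)
  ys <- if (standardize_outcome) as.numeric(scale(y)) else y
  qrX <- qr(cbind(1, Xs))
  if (qrX$rank < ncol(Xs) + 1) {
    aliased <- items[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("collinear (aliased) item(s): ", paste(aliased, collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm(ys ~ Xs)
  sm <- summary(fit)$coefficients
  terms <- data.frame(item_id = items,
                      sprc = unname(stats::coef(fit)[-1]),
                      std_error = unname(sm[-1, "Std. Error"]),
                      p_value = unname(sm[-1, "Pr(>|t|)"]),
                      vif = if (length(items) >= 2) unname(vif(df, items)) else 1,
                      stringsAsFactors = FALSE)
  new_fit_result(terms, "linear_standardized", nrow(df))
}

# separation heuristic for a fitted logistic term on a binary predictor:
# a zero cell in the 2x2 margin, or an exploding Wald SE
term_separated <- function(x, y, se) {
  tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
  any(tab == 0) || se > 50
}

logistic_terms <- function(df, outcome, items) {
  y <- df[[outcome]]
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(sprintf("`%s`", items), collapse = "+")))
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  sm <- suppressWarnings(summary(fit)$coefficients)
  rows <- lapply(items, function(id) {
    nm <- sprintf("`%s`", id)
    nm <- if (nm %in% rownames(sm)) nm else id
    b <- sm[nm, "Estimate"]; se <- sm[nm, "Std. Error"]
    p <- sm[nm, "Pr(>|z|)"]
    sep <- term_separated(df[[id]], y, se)
    data.frame(item_id = id,
               coefficient = b,
               odds_ratio = exp(b),
               ci_low = if (sep) NA_real_ else exp(b - 1.96 * se),
               ci_high = if (sep) NA_real_ else exp(b + 1.96 * se),
               p_value = p,
               separation = sep,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Maximum-likelihood logistic regression with Wald intervals
#'
#' Fits the binary outcome on the risk indicators by maximum likelihood
#' (iteratively reweighted least squares, convergence tolerance 1e-10, at
#' most 100 iterations). Odds ratios are `exp(coefficient)` with 95\% Wald
#' intervals `exp(coefficient +/- 1.96 SE)`. Complete cases only. Complete
#' separation of a term (a zero cell in its 2x2 margin with the outcome, or
#' an exploding standard error) is flagged per term — the estimate diverges
#' and its interval is reported as `NA` — rather than raising an error.
#'
#' @inheritParams fit_linear_standardized
#' @param joint fit one multivariable model over all items (`TRUE`, the
#'   adjusted model) or one univariate model per item (`FALSE`, the crude
#'   model).
#' @return a `screening_fit` with per-term `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value` and a `separation` flag.
#' @examples
#' df <- data.frame(y = rep(c(1, 1, 0, 0), c(20, 10, 10, 20)),
#'                  x = rep(c(1, 0, 1, 0), c(20, 10, 10, 20)))
#' fit_logistic(df, "y", "x")$terms$odds_ratio  # ad/bc = 4
#' @export
fit_logistic <- function(cohort, outcome, items, joint = TRUE) {
  if (joint) {
    df <- complete_case_frame(cohort, outcome, items)
    if (length(unique(df[[outcome]])) < 2)
      stop("outcome has a single class in the complete cases", call. = FALSE)
    terms <- logistic_terms(df, outcome, items)
    return(new_fit_result(terms, "logistic_ml", nrow(df)))
  }
  rows <- lapply(items, function(id) {
    df <- complete_case_frame(cohort, outcome, id)
    logistic_terms(df, outcome, id)
  })
  ns <- vapply(items, function(id)
    nrow(complete_case_frame(cohort, outcome, id)), integer(1))
  new_fit_result(do.call(rbind, rows), "logistic_ml_univariate", max(ns))
}

#' Variance inflation factors
#'
#' For each item, `VIF = 1 / (1 - R^2)` from the ordinary regression of that
#' indicator on all the others (complete cases). Perfect collinearity is
#' reported as `Inf`.
#'
#' @param cohort a `cohort` or data frame.
#' @param items character vector of at least two column names.
#' @return named numeric vector of VIFs (all >= 1).
#' @examples
#' df <- data.frame(a = c(0, 1, 0, 1, 1, 0), b = c(1, 0, 1, 0, 1, 0))
#' vif(df, c("a", "b"))
#' @export
vif <- function(cohort, items) {
  stopifnot(length(items) >= 2)
  df <- as.data.frame(cohort)[items]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  out <- vapply(items, function(id) {
    others <- setdiff(items, id)
    fml <- stats::as.formula(paste(sprintf("`%s`", id), "~",
                                   paste(sprintf("`%s`", others), collapse = "+")))
    r2 <- summary(stats::lm(fml, data = df))$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- items
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged), as used to weight
#' candidate items inside the score-positive risk group.
#'
#' @param x,y equal-length vectors, length >= 3.
#' @return correlation in [-1, 1].
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined: zero variance", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}
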