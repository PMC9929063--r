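#' Binarize an EPDS total at the suspected-depression threshold
#'
#' An Edinburgh Postnatal Depression Scale total of 9 or more (the
#' community-validated Japanese cutoff) codes as 1 — suspected postpartum
#' depression.
#'
#' @param epds_total integer vector of totals in 0-30 (`NA` passes through).
#' @param threshold cutoff, default 9.
#' @return 0/1/`NA` integer vector.
#' @examples
#' binarize_epds(c(8, 9, 30))
#' @export
binarize_epds <- function(epds_total, threshold = 9) {
  stopifnot(threshold >= 1, threshold <= 30)
  bad <- !is.na(epds_total) & (epds_total < 0 | epds_total > 30)
  if (any(bad))
    stop("epds_total out of 0-30 at position(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  as.integer(epds_total >= threshold)
}

#' Exclude items with too few risk-positive records
#'
#' Items carried by fewer than `min_exposed` risk-positive records are too
#' sparse for a stable odds ratio and are excluded with their counts
#' recorded (the original analysis dropped items with 1-4 exposed).
#'
#' @param cohort a `cohort`.
#' @param items candidate item ids.
#' @param min_exposed smallest acceptable risk-positive count (default 5).
#' @return list with `kept` (character) and `excluded` (data frame
#'   `item_id`, `n_exposed`).
#' @export
exclude_sparse_items <- function(cohort, items, min_exposed = 5) {
  stopifnot(min_exposed >= 1)
  n_exposed <- vapply(items, function(id)
    sum(cohort[[id]] == 1, na.rm = TRUE), integer(1))
  excluded <- data.frame(item_id = items[n_exposed < min_exposed],
                         n_exposed = n_exposed[n_exposed < min_exposed],
                         stringsAsFactors = FALSE)
  list(kept = items[n_exposed >= min_exposed], excluded = excluded)
}

#' Crude and adjusted odds ratios of interview items for EPDS >= 9
#'
#' Binarizes the postpartum EPDS total, drops unassessed records, excludes
#' sparse items, then estimates each kept item's crude odds ratio from a
#' univariate logistic fit and its adjusted odds ratio from one
#' multivariable fit entering all kept items of the period together, with
#' 95\% Wald intervals. Separated terms are flagged, not dropped.
#'
#' @param cohort a `cohort` with `epds_total` at least partly filled.
#' @param items candidate items (default: all sheet items in the cohort).
#' @param epds_threshold binarization cutoff (default 9).
#' @param min_exposed sparsity bound (default 5).
#' @return an object of class `epds_association`: list with `table` (data
#'   frame: `item_id`, `n_exposed`, `cOR`, `cCI_low`, `cCI_high`, `cP`,
#'   `aOR`, `aCI_low`, `aCI_high`, `aP`, `excluded_reason`), `n_assessed`,
#'   `n_ge9`, `prevalence_ge9_pct` (one decimal).
#' @export
epds_association <- function(cohort, items = NULL, epds_threshold = 9,
                             min_exposed = 5) {
  period <- attr(cohort, "period")
  items <- items %||% intersect(item_ids(interview_schema(period)),
                                cohort_items(cohort))
  assessed <- cohort[!is.na(cohort$epds_total), , drop = FALSE]
  if (nrow(assessed) == 0) stop("no EPDS-assessed records", call. = FALSE)
  assessed$epds_ge9 <- binarize_epds(assessed$epds_total, epds_threshold)
  if (length(unique(assessed$epds_ge9)) < 2)
    stop("EPDS outcome has a single class", call. = FALSE)
  sp <- exclude_sparse_items(assessed, items, min_exposed)
  if (length(sp$kept) == 0) stop("no items left after sparsity exclusion",
                                 call. = FALSE)
  crude <- fit_logistic(assessed, "epds_ge9", sp$kept, joint = FALSE)
  adj <- fit_logistic(assessed, "epds_ge9", sp$kept, joint = TRUE)
  n_exposed <- vapply(sp$kept, function(id)
    sum(assessed[[id]] == 1, na.rm = TRUE), integer(1))
  tab <- data.frame(item_id = sp$kept, n_exposed = n_exposed,
                    cOR = crude$terms$odds_ratio,
                    cCI_low = crude$terms$ci_low,
                    cCI_high = crude$terms$ci_high,
                    cP = crude$terms$p_value,
                    aOR = adj$terms$odds_ratio,
                    aCI_low = adj$terms$ci_low,
                    aCI_high = adj$terms$ci_high,
                    aP = adj$terms$p_value,
                    excluded_reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(sp$excluded)) {
    ex <- data.frame(item_id = sp$excluded$item_id,
                     n_exposed = sp$excluded$n_exposed,
                     cOR = NA_real_, cCI_low = NA_real_, cCI_high = NA_real_,
                     cP = NA_real_, aOR = NA_real_, aCI_low = NA_real_,
                     aCI_high = NA_real_, aP = NA_real_,
                     excluded_reason = sprintf("sparse (n = %d exposed)",
                                               sp$excluded$n_exposed),
                     stringsAsFactors = FALSE)
    tab <- rbind(tab, ex)
  }
  structure(list(period = period, table = tab,
                 n_assessed = nrow(assessed),
                 n_ge9 = sum(assessed$epds_ge9),
                 prevalence_ge9_pct = pct_half_up(sum(assessed$epds_ge9),
                                                  nrow(assessed), 1),
                 n_joint = adj$n_used),
            class = "epds_association")
}

#' @export
print.epds_association <- function(x, ...) {
  cat("EPDS >= 9 association analysis -", x$period, "\n")
  cat(sprintf("  assessed: %d, EPDS >= 9: %d (%.1f%%)\n",
              x$n_assessed, x$n_ge9, x$prevalence_ge9_pct))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
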