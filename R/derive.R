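ROUNDING_MODES <- c("times100_one_decimal", "times100_nearest_integer")

default_rounding_mode <- function(period) {
  # the published first-visit table keeps one decimal; later sheets use
  # whole points
  if (period == "first_visit") "times100_one_decimal"
  else "times100_nearest_integer"
}

#' Items excluded for crude/adjusted sign reversal
#'
#' An item whose crude (univariate) and adjusted (joint) associations point
#' in opposite risk directions — crude odds ratio above 1 with adjusted
#' below 1, or vice versa, equivalently opposite coefficient signs — is
#' dropped from the scoring model: its adjusted coefficient reflects
#' confounding rather than a usable risk weight. Items with either estimate
#' exactly at the null have no direction and are kept.
#'
#' @param model1 crude `screening_fit` (per-item univariate).
#' @param model2 adjusted `screening_fit` over the same items.
#' @return character vector of excluded item ids.
#' @examples
#' m1 <- data.frame(item_id = "a", odds_ratio = 5.57)
#' m2 <- data.frame(item_id = "a", odds_ratio = 0.35)
#' exclude_sign_reversals(m1, m2)  # "a"
#' @export
exclude_sign_reversals <- function(model1, model2) {
  direction <- function(m) {
    tr <- if (inherits(m, "screening_fit")) m$terms else as.data.frame(m)
    d <- if ("odds_ratio" %in% names(tr)) sign(log(tr$odds_ratio))
         else sign(tr$sprc %||% tr$coefficient)
    stats::setNames(d, tr$item_id)
  }
  d1 <- direction(model1); d2 <- direction(model2)
  shared <- intersect(names(d1), names(d2))
  shared[!is.na(d1[shared]) & !is.na(d2[shared]) &
           d1[shared] * d2[shared] == -1]
}

#' Turn adjusted standardized coefficients into item scores
#'
#' Each retained item's score is its standardized partial regression
#' coefficient times 100, rounded half-up either to one decimal or to the
#' nearest whole point. Negative coefficients must have been excluded
#' upstream (sign-reversal step); one reaching this stage is a pipeline
#' ordering error.
#'
#' @param model2 an adjusted `screening_fit`, or a data frame with columns
#'   `item_id` and `sprc` (e.g. a packaged coefficient fixture).
#' @param rounding_mode `"times100_one_decimal"` or
#'   `"times100_nearest_integer"`.
#' @param period optional period tag carried on the table.
#' @return an object of class `scoring_table`: list with `period`,
#'   `entries` (data frame `item_id`, `sprc`, `score`) and `rounding_mode`.
#' @examples
#' score_items(data.frame(item_id = "maternal_age_lt25", sprc = 0.212),
#'             "times100_one_decimal")$entries$score  # 21.2
#' @export
score_items <- function(model2, rounding_mode, period = NULL) {
  rounding_mode <- match.arg(rounding_mode, ROUNDING_MODES)
  tr <- if (inherits(model2, "screening_fit")) model2$terms
        else as.data.frame(model2)
  if (!all(c("item_id", "sprc") %in% names(tr)))
    stop("`model2` must carry item_id and sprc", call. = FALSE)
  if (any(tr$sprc < 0))
    stop("negative standardized coefficient(s) reached scoring (",
         paste(tr$item_id[tr$sprc < 0], collapse = ", "),
         "); sign-reversal exclusion must run first", call. = FALSE)
  digits <- if (rounding_mode == "times100_one_decimal") 1L else 0L
  entries <- data.frame(item_id = tr$item_id, sprc = tr$sprc,
                        score = round_half_up(tr$sprc * 100, digits),
                        stringsAsFactors = FALSE)
  structure(list(period = period, entries = entries,
                 rounding_mode = rounding_mode), class = "scoring_table")
}

#' @export
print.scoring_table <- function(x, ...) {
  cat("Scoring table (", x$rounding_mode,
      if (!is.null(x$period)) paste0(", ", x$period), ")\n", sep = "")
  print(x$entries, row.names = FALSE)
  cat("  maximum total:", sum(x$entries$score), "points\n")
  invisible(x)
}

scoring_total <- function(cohort, scoring) {
  tot <- rep(0, nrow(cohort))
  for (i in seq_len(nrow(scoring$entries))) {
    id <- scoring$entries$item_id[i]
    if (!id %in% names(cohort)) next
    x <- cohort[[id]]
    x[is.na(x)] <- 0L  # missing answers contribute no points
    tot <- tot + x * scoring$entries$score[i]
  }
  tot
}

#' ROC cutoff of a scoring table on a cohort
#'
#' Computes each record's total score (missing indicators contribute 0
#' points), builds the ROC curve against the outcome and returns the Youden
#' cutoff with its operating characteristics.
#'
#' @param cohort a `cohort`.
#' @param scoring a `scoring_table`.
#' @param outcome binary outcome column (default `"admin_cooperation"`).
#' @return list with `threshold`, `auc`, `sensitivity`, `specificity` and
#'   the full `roc` curve.
#' @export
derive_cutoff <- function(cohort, scoring, outcome = "admin_cooperation") {
  tot <- scoring_total(cohort, scoring)
  y <- cohort[[outcome]]
  ok <- !is.na(y)
  curve <- roc_curve(tot[ok], y[ok])
  cut <- select_cutoff(curve)
  list(threshold = cut$threshold, auc = curve$auc,
       sensitivity = cut$sensitivity, specificity = cut$specificity,
       roc = curve)
}

#' Second-stage items by prevalence among outcome-positives
#'
#' Selects the items whose risk-indicator prevalence among outcome-positive
#' (public-health-center cooperation) records reaches the threshold
#' fraction. Candidates may include items excluded from scoring. The
#' boundary is inclusive by default (a prevalence of exactly 30\% selects).
#'
#' @param cohort a `cohort`.
#' @param outcome binary outcome column.
#' @param candidate_items items to consider.
#' @param threshold prevalence fraction (default 0.30).
#' @param inclusive select at exactly the threshold (default `TRUE`).
#' @return character vector of selected item ids.
#' @export
step2_items_by_prevalence <- function(cohort, outcome = "admin_cooperation",
                                      candidate_items,
                                      threshold = 0.30, inclusive = TRUE) {
  pos <- cohort[!is.na(cohort[[outcome]]) & cohort[[outcome]] == 1, ,
                drop = FALSE]
  if (nrow(pos) == 0)
    stop("no outcome-positive records: prevalence undefined", call. = FALSE)
  prev <- vapply(candidate_items, function(id) {
    x <- pos[[id]]
    if (is.null(x) || all(is.na(x))) return(NA_real_)
    mean(x == 1, na.rm = TRUE)
  }, numeric(1))
  keep <- if (inclusive) prev >= threshold else prev > threshold
  candidate_items[!is.na(prev) & keep]
}

#' Second-stage items by weighted rank correlation
#'
#' On the first-stage-positive subset, each candidate item's Spearman
#' correlation with the outcome is weighted by a factor (10 by default);
#' items reaching the minimum weighted value (2 points, i.e. rho >= 0.2)
#' are selected. Zero-variance items on the subset are skipped with a
#' warning.
#'
#' @param cohort the cohort restricted to first-stage positives.
#' @param outcome binary outcome column.
#' @param items candidate item ids.
#' @param weight multiplier applied to the correlation (default 10).
#' @param min_points selection bound on the weighted value (default 2).
#' @return character vector of selected item ids.
#' @export
step2_items_by_weighted_spearman <- function(cohort,
                                             outcome = "admin_cooperation",
                                             items, weight = 10,
                                             min_points = 2) {
  if (nrow(cohort) == 0) stop("empty first-stage subset", call. = FALSE)
  y <- cohort[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome has a single class in the first-stage subset",
         call. = FALSE)
  sel <- character()
  for (id in items) {
    x <- cohort[[id]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) {
      warning("item skipped (zero variance on subset): ", id, call. = FALSE)
      next
    }
    if (spearman_rho(x[ok], y[ok]) * weight >= min_points)
      sel <- c(sel, id)
  }
  sel
}

#' Freeze a screening tool definition
#'
#' Binds a scoring table, the first-stage score threshold, the second-stage
#' any-of item set, the third-stage minimum-count item set and optional
#' mandatory-referral items into a serializable screening tool. Step item
#' sets must belong to the period's sheet but may include items absent from
#' the scoring table.
#'
#' @param scoring a `scoring_table`.
#' @param step1_threshold total-score cutoff for the first stage.
#' @param step2_items any-of item set of the second stage.
#' @param step3_items item set of the third stage.
#' @param step3_min_count minimum risk-positive count in `step3_items`
#'   (>= 1).
#' @param period care period.
#' @param mandatory_referral_items items whose risk-positive answer
#'   short-circuits to a positive screen regardless of score.
#' @param step_semantics `"sequential_narrowing"` (each stage filters the
#'   previous stage's positives, the default) or `"union"` (any stage's
#'   criterion alone flags the record).
#' @param provenance free text (`"derived"` or `"transcribed_from_paper"`).
#' @param derivation_metrics optional list of ROC metrics to carry along.
#' @return an object of class `screening_tool`.
#' @export
assemble_tool <- function(scoring, step1_threshold, step2_items, step3_items,
                          step3_min_count, period,
                          mandatory_referral_items = character(),
                          step_semantics = c("sequential_narrowing", "union"),
                          provenance = "derived",
                          derivation_metrics = NULL) {
  step_semantics <- match.arg(step_semantics)
  assert_period(period)
  stopifnot(inherits(scoring, "scoring_table"))
  if (step3_min_count < 1)
    stop("`step3_min_count` must be >= 1", call. = FALSE)
  if (step_semantics == "sequential_narrowing" &&
      (length(step2_items) == 0 || length(step3_items) == 0))
    stop("sequential semantics require non-empty step-2 and step-3 item sets",
         call. = FALSE)
  ids <- item_ids(interview_schema(period))
  for (set in list(step2_items, step3_items, mandatory_referral_items)) {
    bad <- setdiff(set, ids)
    if (length(bad))
      stop("step item(s) not on the ", period, " sheet: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(period = period, scoring = scoring,
                 step1_threshold = step1_threshold,
                 step2 = list(rule = "any_of", items = step2_items),
                 step3 = list(min_count = as.integer(step3_min_count),
                              items = step3_items),
                 mandatory_referral_items = mandatory_referral_items,
                 step_semantics = step_semantics,
                 provenance = provenance,
                 derivation_metrics = derivation_metrics),
            class = "screening_tool")
}

#' @export
print.screening_tool <- function(x, ...) {
  cat("Stepwise screening tool -", x$period, "(", x$provenance, ")\n")
  cat("  STEP-1: total score >=", x$step1_threshold, "points over",
      nrow(x$scoring$entries), "items\n")
  cat("  STEP-2: any of", paste(x$step2$items, collapse = ", "), "\n")
  cat("  STEP-3: at least", x$step3$min_count, "of",
      paste(x$step3$items, collapse = ", "), "\n")
  if (length(x$mandatory_referral_items))
    cat("  mandatory referral:",
        paste(x$mandatory_referral_items, collapse = ", "), "\n")
  invisible(x)
}

#' Accept or reject a derived tool by AUC
#'
#' A candidate tool is accepted when its first-stage AUC reaches the
#' screening-acceptability bound (0.70 by default, boundary inclusive);
#' otherwise it is rejected with the metric recorded, as happened to the
#' third-trimester sheet (AUC 0.46).
#'
#' @param metrics list with at least `auc` (as from [derive_cutoff()]).
#' @param min_auc acceptability bound.
#' @return list with `accepted` flag and `rejection_reason` (`NULL` when
#'   accepted).
#' @export
accept_or_reject_tool <- function(metrics, min_auc = 0.70) {
  auc <- if (is.list(metrics)) metrics$auc else metrics
  if (auc >= min_auc) list(accepted = TRUE, rejection_reason = NULL)
  else list(accepted = FALSE,
            rejection_reason = sprintf(
              "AUC %.2f below the screening-acceptability bound %.2f",
              auc, min_auc))
}

#' Derive a stepwise screening tool from a cohort
#'
#' Runs the full derivation pipeline on one period's cohort:
#' \enumerate{
#'   \item crude (univariate logistic) and all-item adjusted fits;
#'   \item exclusion of sign-reversed items, mandatory-referral items and
#'     items unanalyzable in the complete cases (all-missing or
#'     zero-variance);
#'   \item one adjusted refit (joint standardized linear for the
#'     coefficients, joint logistic for odds ratios) on the retained items —
#'     scores are read from this single fit, never refit per exclusion;
#'   \item coefficient-times-100 scoring and the ROC/Youden cutoff;
#'   \item AUC acceptance check;
#'   \item second-stage item selection by outcome-positive prevalence or by
#'     weighted rank correlation within the first-stage positives;
#'   \item assembly with the configured third-stage rule.
#' }
#'
#' @param cohort a `cohort`.
#' @param outcome binary outcome column.
#' @param items candidate items (default: all sheet items present in the
#'   cohort).
#' @param config list of settings: `rounding_mode` (default per period),
#'   `mandatory_referral_items`, `step2_method` (`"prevalence"` or
#'   `"weighted_spearman"`), `step2_threshold` (0.30), `step2_weight` (10),
#'   `step2_min_points` (2), `step3_items` (required for an accepted tool),
#'   `step3_min_count` (default 1), `min_auc` (0.70), `step_semantics`.
#' @return an object of class `derivation_report`: list with `accepted`,
#'   `tool` (`NULL` when rejected), `model1`, `model2`, `model2_linear`,
#'   `excluded_sign_reversal`, `excluded_other`, `scoring`, `cutoff`,
#'   `rejection_reason`.
#' @export
derive_tool <- function(cohort, outcome = "admin_cooperation", items = NULL,
                        config = list()) {
  period <- attr(cohort, "period")
  schema_ids <- item_ids(interview_schema(period))
  items <- items %||% intersect(schema_ids, cohort_items(cohort))
  mandatory <- config$mandatory_referral_items %||% character()
  rounding <- config$rounding_mode %||% default_rounding_mode(period)
  min_auc <- config$min_auc %||% 0.70

  # drop items that cannot enter a joint fit
  excluded_other <- list()
  analyzable <- character()
  for (id in setdiff(items, mandatory)) {
    x <- cohort[[id]]
    if (all(is.na(x)) || stats::sd(x, na.rm = TRUE) == 0)
      excluded_other[[id]] <- "insufficient data (missing or constant)"
    else analyzable <- c(analyzable, id)
  }
  for (id in intersect(items, mandatory))
    excluded_other[[id]] <- "mandatory referral item (screened outside scoring)"

  model1 <- fit_logistic(cohort, outcome, analyzable, joint = FALSE)
  all_factor <- fit_linear_standardized(cohort, outcome, analyzable)
  reversed <- exclude_sign_reversals(model1, all_factor)
  retained <- setdiff(analyzable, reversed)

  model2_linear <- fit_linear_standardized(cohort, outcome, retained)
  model2 <- fit_logistic(cohort, outcome, retained, joint = TRUE)
  # a residual negative coefficient after exclusion is dropped from the
  # scoring table (recorded), without refitting the single adjusted model
  neg <- model2_linear$terms$item_id[model2_linear$terms$sprc < 0]
  for (id in neg) excluded_other[[id]] <- "negative adjusted coefficient"
  score_terms <- model2_linear$terms[!model2_linear$terms$item_id %in% neg, ]
  scoring <- score_items(score_terms, rounding, period)
  cut <- derive_cutoff(cohort, scoring, outcome)
  verdict <- accept_or_reject_tool(cut, min_auc)

  tool <- NULL
  if (verdict$accepted) {
    method <- config$step2_method %||% "prevalence"
    step2 <- if (method == "prevalence") {
      step2_items_by_prevalence(
        cohort, outcome, candidate_items = items,
        threshold = config$step2_threshold %||% 0.30,
        inclusive = config$step2_inclusive %||% TRUE)
    } else {
      tot <- scoring_total(cohort, scoring)
      step2_items_by_weighted_spearman(
        cohort[tot >= cut$threshold, , drop = FALSE], outcome,
        items = setdiff(items, mandatory),
        weight = config$step2_weight %||% 10,
        min_points = config$step2_min_points %||% 2)
    }
    step3_items <- config$step3_items %||% step2
    tool <- assemble_tool(
      scoring, cut$threshold, step2, step3_items,
      step3_min_count = config$step3_min_count %||% 1L,
      period = period, mandatory_referral_items = mandatory,
      step_semantics = config$step_semantics %||% "sequential_narrowing",
      provenance = sprintf("derived from cohort (%s)",
                           attr(cohort, "provenance")),
      derivation_metrics = cut[c("auc", "sensitivity", "specificity")])
  }
  structure(list(period = period, accepted = verdict$accepted,
                 rejection_reason = verdict$rejection_reason, tool = tool,
                 model1 = model1, model2 = model2,
                 model2_linear = model2_linear,
                 excluded_sign_reversal = reversed,
                 excluded_other = excluded_other,
                 scoring = scoring,
                 cutoff = cut[c("threshold", "auc", "sensitivity",
                                "specificity")]),
            class = "derivation_report")
}

#' @export
print.derivation_report <- function(x, ...) {
  cat("Screening-tool derivation -", x$period, "\n")
  cat("  sign-reversal exclusions:",
      if (length(x$excluded_sign_reversal))
        paste(x$excluded_sign_reversal, collapse = ", ") else "none", "\n")
  if (length(x$excluded_other))
    for (id in names(x$excluded_other))
      cat("  excluded:", id, "-", x$excluded_other[[id]], "\n")
  cat(sprintf("  cutoff %s points, AUC %.2f (sens %.2f, spec %.2f)\n",
              format(x$cutoff$threshold), x$cutoff$auc,
              x$cutoff$sensitivity, x$cutoff$specificity))
  cat("  verdict:", if (x$accepted) "ACCEPTED"
      else paste("REJECTED -", x$rejection_reason), "\n")
  invisible(x)
}
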