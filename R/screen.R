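STAGES <- c("negative_step1", "negative_step2", "negative_step3", "positive")

# named 0/1/NA indicator vector from whatever represents one woman
record_indicators <- function(record) {
  if (inherits(record, "interview_record")) return(record$indicators)
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    cols <- setdiff(names(record), RESERVED_COLUMNS)
    return(stats::setNames(as.integer(unlist(record[1, cols])), cols))
  }
  v <- unlist(record)
  stats::setNames(as.integer(v), names(v))
}

record_period <- function(record) {
  if (inherits(record, "interview_record")) return(record$period)
  if (is.data.frame(record) && "period" %in% names(record))
    return(record$period[1])
  NULL
}

#' Total screening score of one record
#'
#' Sum of the scoring-table points of the record's risk-positive items;
#' items that are missing or absent from the scoring table contribute 0
#' points (the screen-negative direction).
#'
#' @param record an `interview_record`, a one-row cohort, or a named 0/1
#'   vector of indicators.
#' @param tool a `screening_tool`.
#' @return total score in points.
#' @examples
#' tool <- reference_tool("first_visit")
#' total_score(c(maternal_age_lt25 = 1), tool)  # 21.2
#' @export
total_score <- function(record, tool) {
  stopifnot(inherits(tool, "screening_tool"))
  ind <- record_indicators(record)
  e <- tool$scoring$entries
  x <- ind[e$item_id]
  x[is.na(x)] <- 0L
  sum(x * e$score)
}

any_risk <- function(ind, items) {
  x <- ind[items]
  any(!is.na(x) & x == 1L)
}

count_risk <- function(ind, items) {
  x <- ind[items]
  sum(!is.na(x) & x == 1L)
}

#' Screen one record with a frozen tool
#'
#' Sequential evaluation: STEP-1 requires the total score to reach the
#' threshold; STEP-2 requires at least one risk-positive answer among its
#' any-of items; STEP-3 requires at least `min_count` risk-positive answers
#' among its items. A risk-positive mandatory-referral item short-circuits
#' to a positive screen regardless of score. Under `"union"` semantics any
#' single stage's criterion flags the record.
#'
#' @param record as in [total_score()].
#' @param tool a `screening_tool` of the record's period.
#' @return an object of class `screening_result`: list with `record_id`,
#'   `total_score`, `stage_reached` (one of `negative_step1`,
#'   `negative_step2`, `negative_step3`, `positive`), `mandatory_referral`,
#'   `missing_items_used`.
#' @examples
#' tool <- reference_tool("first_visit")
#' apply_tool(c(partner_status = 1, maternal_mental_disorder = 1,
#'              depression_symptoms = 1), tool)$stage_reached
#' @export
apply_tool <- function(record, tool) {
  stopifnot(inherits(tool, "screening_tool"))
  rp <- record_period(record)
  if (!is.null(rp) && !identical(rp, tool$period))
    stop("record period (", rp, ") does not match tool period (",
         tool$period, ")", call. = FALSE)
  ind <- record_indicators(record)
  tot <- total_score(record, tool)
  miss <- sum(is.na(ind[tool$scoring$entries$item_id]))
  rid <- if (inherits(record, "interview_record")) record$record_id
         else if (is.data.frame(record) && "record_id" %in% names(record))
           record$record_id[1] else NA_character_
  res <- function(stage, mandatory = FALSE)
    structure(list(record_id = rid, total_score = tot, stage_reached = stage,
                   mandatory_referral = mandatory, missing_items_used = miss),
              class = "screening_result")
  if (length(tool$mandatory_referral_items) &&
      any_risk(ind, tool$mandatory_referral_items))
    return(res("positive", mandatory = TRUE))
  s1 <- tot >= tool$step1_threshold
  s2 <- any_risk(ind, tool$step2$items)
  s3 <- count_risk(ind, tool$step3$items) >= tool$step3$min_count
  if (tool$step_semantics == "union")
    return(res(if (s1 || s2 || s3) "positive" else "negative_step1"))
  if (!s1) return(res("negative_step1"))
  if (!s2) return(res("negative_step2"))
  if (!s3) return(res("negative_step3"))
  res("positive")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Screening result", if (!is.na(x$record_id)) x$record_id, ":",
      x$stage_reached,
      sprintf("(total %s points%s)\n", format(x$total_score),
              if (x$mandatory_referral) ", mandatory referral" else ""))
  invisible(x)
}

#' Screen a cohort and report the stage funnel
#'
#' Applies a frozen tool to every record and aggregates a stage-by-stage
#' funnel: how many records survive each step, what share of the screened
#' cohort that is, and — when the outcome column is observed — how many of
#' each stage's survivors had the outcome, as a percentage of that stage.
#' Percentages are rounded half-up to the whole percent by default.
#'
#' @param cohort a `cohort` matching the tool's period.
#' @param tool a `screening_tool`.
#' @param outcome outcome column for overlap reporting.
#' @param digits decimal places of reported percentages.
#' @return list with `results` (data frame: `record_id`, `total_score`,
#'   `stage_reached`, `mandatory_referral`, `missing_items_used`) and
#'   `funnel` (a `funnel_report`).
#' @export
screen_cohort <- function(cohort, tool, outcome = "admin_cooperation",
                          digits = 0) {
  rows <- lapply(seq_len(nrow(cohort)), function(i)
    apply_tool(cohort[i, , drop = FALSE], tool))
  results <- data.frame(
    record_id = vapply(rows, `[[`, character(1), "record_id"),
    total_score = vapply(rows, `[[`, numeric(1), "total_score"),
    stage_reached = vapply(rows, `[[`, character(1), "stage_reached"),
    mandatory_referral = vapply(rows, `[[`, logical(1), "mandatory_referral"),
    missing_items_used = vapply(rows, `[[`, integer(1), "missing_items_used"),
    stringsAsFactors = FALSE)
  stage <- factor(results$stage_reached, levels = STAGES)
  # survivors of step k = records that reached beyond it
  surv1 <- sum(stage != "negative_step1")
  surv2 <- sum(!stage %in% c("negative_step1", "negative_step2"))
  surv3 <- sum(stage == "positive")
  y <- cohort[[outcome]]
  overlap <- function(keep) {
    if (all(is.na(y))) NA_integer_ else sum(y == 1 & keep, na.rm = TRUE)
  }
  k1 <- stage != "negative_step1"
  k2 <- !stage %in% c("negative_step1", "negative_step2")
  k3 <- stage == "positive"
  funnel <- data.frame(
    stage = c("step1", "step2", "step3"),
    n_surviving = c(surv1, surv2, surv3),
    pct_of_screened = pct_half_up(c(surv1, surv2, surv3), nrow(cohort),
                                  digits),
    outcome_positive = c(overlap(k1), overlap(k2), overlap(k3)),
    stringsAsFactors = FALSE)
  funnel$outcome_pct_of_stage <- ifelse(
    funnel$n_surviving > 0 & !is.na(funnel$outcome_positive),
    pct_half_up(funnel$outcome_positive, pmax(funnel$n_surviving, 1), digits),
    NA_real_)
  rep <- structure(list(n_screened = nrow(cohort), stages = funnel,
                        n_positive = surv3,
                        pct_positive = pct_half_up(surv3, nrow(cohort),
                                                   max(digits, 1)),
                        by_stage = table(stage)),
                   class = "funnel_report")
  list(results = results, funnel = rep)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Screening funnel:", x$n_screened, "records screened\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("  final positive: %d (%s%% of screened)\n",
              x$n_positive, format(x$pct_positive)))
  invisible(x)
}

#' Packaged reference screening tools
#'
#' Loads the shipped first-visit or second-trimester tool (transcribed
#' published scoring tables, thresholds 22 and 14 points, step item sets and
#' mandatory-referral items). No third-trimester tool exists: that sheet's
#' candidate tool was rejected (AUC 0.46).
#'
#' @param period `"first_visit"` or `"second_trimester"`.
#' @return a `screening_tool`.
#' @examples
#' reference_tool("first_visit")$step1_threshold  # 22
#' @export
reference_tool <- function(period = c("first_visit", "second_trimester")) {
  period <- match.arg(period)
  read_tool_json(extdata_path(paste0("tool_", period, ".json")))
}

#' Published screening-funnel and EPDS counts
#'
#' The stage-by-stage counts of the original derivation cohorts (558 and
#' 483 analyzed records, their step survivors, and the public-health-center
#' cooperation overlap at each stage) and the postpartum EPDS >= 9 counts
#' among each period's completers — packaged for funnel-arithmetic checks
#' and worked examples.
#'
#' @return nested list mirroring the packaged JSON.
#' @export
paper_counts <- function() {
  read_packaged_json("screening_funnel_counts.json")
}
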