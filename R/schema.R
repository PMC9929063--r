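#' Interview-sheet schema for a care period
#'
#' Loads the packaged structured interview sheet for one antenatal/postpartum
#' care period. Each item carries the set of answer strings on the
#' non-risk ("positive") side and on the risk ("negative") side; risk-coding
#' turns a raw answer into a binary indicator that is 1 exactly on the
#' negative side. The first-visit sheet has 14 items, the second-trimester
#' sheet 11, the third-trimester sheet 8 and the postpartum sheet 7
#' (counting the EPDS row).
#'
#' @param period one of `"first_visit"`, `"second_trimester"`,
#'   `"third_trimester"`, `"postpartum"`.
#' @return An object of class `period_schema`: a list with `period` and
#'   `items` (a list of item entries, each with `item_id`, `label`,
#'   `positive`, `negative`).
#' @examples
#' sch <- interview_schema("first_visit")
#' length(sch$items)
#' item_ids(sch)
#' @export
interview_schema <- function(period) {
  assert_period(period)
  raw <- read_packaged_json("interview_schema.json")
  items <- lapply(raw$periods[[period]]$items, function(it) {
    list(item_id = it$item_id, label = it$label,
         positive = vapply(it$positive, identity, character(1)),
         negative = vapply(it$negative, identity, character(1)))
  })
  structure(list(period = period, items = items), class = "period_schema")
}

#' @export
print.period_schema <- function(x, ...) {
  cat("Interview sheet schema:", x$period, "-", length(x$items), "items\n")
  for (it in x$items)
    cat(sprintf("  %-26s %s\n", it$item_id, it$label))
  invisible(x)
}

#' Item identifiers of a schema
#'
#' @param schema a `period_schema`.
#' @return character vector of item ids, in sheet order.
#' @export
item_ids <- function(schema) {
  stopifnot(inherits(schema, "period_schema"))
  vapply(schema$items, `[[`, character(1), "item_id")
}

schema_item <- function(schema, id) {
  for (it in schema$items) if (it$item_id == id) return(it)
  stop("unknown item_id for period ", schema$period, ": ", id, call. = FALSE)
}

#' Risk-code raw questionnaire answers into a record
#'
#' Converts raw answer strings into binary risk indicators against a period
#' schema: 1 when the answer lies on the item's risk ("negative") side,
#' 0 on the non-risk side. Matching is case-insensitive after whitespace
#' trimming. Items without a supplied answer become missing (`NA`).
#'
#' @param raw_answers named character vector or list, names are item ids.
#' @param schema a `period_schema`.
#' @param record_id identifier for the record (default `"r1"`).
#' @return An object of class `interview_record`: list with `record_id`,
#'   `period`, and `indicators` (named integer vector over all schema items,
#'   values 0/1/`NA`), plus `admin_cooperation`, `hospital_support`,
#'   `epds_total` slots initialised to `NA`.
#' @examples
#' sch <- interview_schema("first_visit")
#' r <- encode_record(c(maternal_age_lt25 = ">=25",
#'                      maternal_feelings = "Confused"), sch)
#' r$indicators[c("maternal_age_lt25", "maternal_feelings")]
#' @export
encode_record <- function(raw_answers, schema, record_id = "r1") {
  stopifnot(inherits(schema, "period_schema"))
  ids <- item_ids(schema)
  ans <- as.list(raw_answers)
  unknown <- setdiff(names(ans), ids)
  if (length(unknown))
    stop("unknown item_id(s) for period ", schema$period, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ind <- rep(NA_integer_, length(ids))
  names(ind) <- ids
  for (id in names(ans)) {
    if (is.null(ans[[id]]) || is.na(ans[[id]])) next
    it <- schema_item(schema, id)
    a <- normalize_answer(as.character(ans[[id]]))
    if (a %in% normalize_answer(it$negative)) {
      ind[[id]] <- 1L
    } else if (a %in% normalize_answer(it$positive)) {
      ind[[id]] <- 0L
    } else {
      stop("answer not recognised for item '", id, "': \"", ans[[id]],
           "\" (not in the positive or negative answer set)", call. = FALSE)
    }
  }
  structure(list(record_id = record_id, period = schema$period,
                 indicators = ind, admin_cooperation = NA_integer_,
                 hospital_support = NA_integer_, epds_total = NA_integer_),
            class = "interview_record")
}

#' Decode a binary indicator back to its risk label
#'
#' Inverse of the risk-coding: returns the canonical (first-listed) answer
#' string on the indicated side, so that re-encoding reproduces the
#' indicator.
#'
#' @param indicator 0, 1 or `NA`.
#' @param item_id item identifier.
#' @param schema a `period_schema`.
#' @return a canonical answer string, or `NA` for a missing indicator.
#' @export
decode_indicator <- function(indicator, item_id, schema) {
  it <- schema_item(schema, item_id)
  if (is.na(indicator)) return(NA_character_)
  if (indicator == 1L) it$negative[[1]] else it$positive[[1]]
}

#' @export
print.interview_record <- function(x, ...) {
  cat("Interview record", x$record_id, "(", x$period, ")\n")
  flagged <- names(x$indicators)[!is.na(x$indicators) & x$indicators == 1L]
  cat("  risk-positive items:",
      if (length(flagged)) paste(flagged, collapse = ", ") else "none", "\n")
  cat("  missing items:", sum(is.na(x$indicators)), "\n")
  invisible(x)
}

#' Construct a cohort from a data frame of indicators
#'
#' A cohort is a data frame with one row per woman: `record_id`, `period`,
#' one 0/1/`NA` column per schema item, and the columns `admin_cooperation`
#' (needed public-health-center collaboration), `hospital_support` and
#' `epds_total`. The object carries the period and a free-text provenance.
#'
#' @param df data frame with the columns above (missing outcome/EPDS columns
#'   are added as `NA`).
#' @param period the sheet period; defaults to the unique value of
#'   `df$period`.
#' @param provenance free text describing origin (file path or simulation
#'   parameters).
#' @return a `cohort` object (data frame subclass).
#' @export
as_cohort <- function(df, period = NULL, provenance = "unspecified") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(period)) {
    if (!"period" %in% names(df) || !length(df$period))
      stop("`period` not given and not present in `df`", call. = FALSE)
    period <- unique(df$period)[1]
  }
  assert_period(period)
  if (!"record_id" %in% names(df))
    df$record_id <- sprintf("r%04d", seq_len(nrow(df)))
  if (!"period" %in% names(df)) df$period <- period
  for (col in c("admin_cooperation", "hospital_support", "epds_total"))
    if (!col %in% names(df)) df[[col]] <- NA_integer_
  icols <- setdiff(names(df), RESERVED_COLUMNS)
  for (col in c(icols, "admin_cooperation", "hospital_support", "epds_total"))
    df[[col]] <- as.integer(df[[col]])
  df <- df[c("record_id", "period", icols,
             "admin_cooperation", "hospital_support", "epds_total")]
  structure(df, period = period, provenance = provenance,
            class = c("cohort", "data.frame"))
}

#' Item indicator columns of a cohort
#'
#' @param cohort a `cohort`.
#' @return character vector of the indicator column names.
#' @export
cohort_items <- function(cohort) setdiff(names(cohort), RESERVED_COLUMNS)

#' @export
print.cohort <- function(x, ...) {
  cat("Interview cohort:", nrow(x), "records,", attr(x, "period"), "period\n")
  cat("  items:", paste(cohort_items(x), collapse = ", "), "\n")
  if (any(!is.na(x$admin_cooperation)))
    cat("  admin cooperation: ", sum(x$admin_cooperation == 1, na.rm = TRUE),
        " positive\n", sep = "")
  if (any(!is.na(x$epds_total)))
    cat("  EPDS assessed: ", sum(!is.na(x$epds_total)), " records\n", sep = "")
  cat("  provenance:", attr(x, "provenance"), "\n")
  invisible(x)
}

#' Validate a cohort against a period schema
#'
#' Report-only check: counts missing indicators per item and flags records
#' violating basic invariants (period mismatch, indicator values outside
#' \{0, 1, NA\}, EPDS total outside 0-30). Never modifies the cohort.
#'
#' @param cohort a `cohort` (or plain data frame in cohort layout).
#' @param schema the matching `period_schema`.
#' @return list of class `cohort_validation` with `n_records`,
#'   `missing_by_item` (named integer), `unknown_items`, and `problems`
#'   (data frame `record_id`, `problem`).
#' @export
validate_cohort <- function(cohort, schema) {
  stopifnot(inherits(schema, "period_schema"))
  ids <- item_ids(schema)
  icols <- intersect(cohort_items(cohort), ids)
  unknown <- setdiff(cohort_items(cohort), ids)
  missing_by_item <- vapply(ids, function(id) {
    if (!id %in% names(cohort)) nrow(cohort)
    else sum(is.na(cohort[[id]]))
  }, integer(1))
  probs <- list()
  flag <- function(rid, what) probs[[length(probs) + 1L]] <<-
    data.frame(record_id = rid, problem = what, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cohort))) {
    rid <- cohort$record_id[i]
    if (!identical(cohort$period[i], schema$period))
      flag(rid, paste0("period mismatch: ", cohort$period[i]))
    for (id in icols) {
      v <- cohort[[id]][i]
      if (!is.na(v) && !v %in% c(0L, 1L))
        flag(rid, paste0("indicator not 0/1: ", id, "=", v))
    }
    ep <- cohort$epds_total[i]
    if (!is.na(ep) && (ep < 0 || ep > 30))
      flag(rid, paste0("epds_total out of 0-30: ", ep))
  }
  problems <- if (length(probs)) do.call(rbind, probs)
  else data.frame(record_id = character(), problem = character(),
                  stringsAsFactors = FALSE)
  structure(list(n_records = nrow(cohort), missing_by_item = missing_by_item,
                 unknown_items = unknown, problems = problems),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation:", x$n_records, "records\n")
  tot <- sum(x$missing_by_item)
  cat("  missing indicator cells:", tot, "\n")
  if (length(x$unknown_items))
    cat("  columns not in schema:", paste(x$unknown_items, collapse = ", "), "\n")
  cat("  records with problems:", length(unique(x$problems$record_id)), "\n")
  invisible(x)
}
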