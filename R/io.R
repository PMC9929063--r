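TOOL_SCHEMA_VERSION <- 1L

#' Write a cohort to CSV
#'
#' One row per record, columns `record_id, period, <item columns>,
#' admin_cooperation, hospital_support, epds_total`; missing cells are
#' written empty.
#'
#' @param cohort a `cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Parses and type-checks a cohort file: indicator cells must be 0, 1 or
#' empty; `epds_total` must lie in 0-30; with a schema given, indicator
#' columns must be sheet items. Violations raise named errors with row
#' numbers.
#'
#' @param path CSV file as written by [write_cohort_csv()].
#' @param schema optional `period_schema` to check columns against.
#' @param period expected period (default: taken from the file).
#' @return a `cohort` with provenance set to the path.
#' @export
read_cohort_csv <- function(path, schema = NULL, period = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(record_id = "character"))
  if (nrow(df) == 0) stop("empty cohort file: ", path, call. = FALSE)
  need <- c("record_id", "period")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  icols <- setdiff(names(df), RESERVED_COLUMNS)
  if (!is.null(schema)) {
    unknown <- setdiff(icols, item_ids(schema))
    if (length(unknown))
      stop("unknown indicator column(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  for (col in icols) {
    v <- df[[col]]
    bad <- which(!is.na(v) & !v %in% c(0, 1))
    if (length(bad))
      stop("indicator `", col, "` not 0/1 at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("epds_total" %in% names(df)) {
    v <- df$epds_total
    bad <- which(!is.na(v) & (v < 0 | v > 30))
    if (length(bad))
      stop("epds_total out of 0-30 at row(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  as_cohort(df, period = period %||% unique(df$period)[1],
            provenance = path)
}

tool_to_list <- function(tool) {
  list(format = "screening_tool", version = TOOL_SCHEMA_VERSION,
       period = tool$period, provenance = tool$provenance,
       rounding_mode = tool$scoring$rounding_mode,
       scoring = lapply(seq_len(nrow(tool$scoring$entries)), function(i)
         list(item_id = tool$scoring$entries$item_id[i],
              sprc = tool$scoring$entries$sprc[i],
              score = tool$scoring$entries$score[i])),
       step1_threshold = tool$step1_threshold,
       step2 = list(rule = tool$step2$rule, items = as.list(tool$step2$items)),
       step3 = list(min_count = tool$step3$min_count,
                    items = as.list(tool$step3$items)),
       mandatory_referral_items = as.list(tool$mandatory_referral_items),
       step_semantics = tool$step_semantics,
       derivation_metrics = tool$derivation_metrics)
}

#' Serialize a screening tool to JSON
#'
#' Versioned, lossless serialization; [read_tool_json()] restores an
#' identical definition.
#'
#' @param tool a `screening_tool`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tool_json <- function(tool, path) {
  stopifnot(inherits(tool, "screening_tool"))
  jsonlite::write_json(tool_to_list(tool), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a screening tool from JSON
#'
#' Validates the format tag, schema version and field types before
#' constructing the tool.
#'
#' @param path a tool JSON file.
#' @return a `screening_tool`.
#' @examples
#' tool <- reference_tool("second_trimester")
#' tool$step1_threshold  # 14
#' @export
read_tool_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path)
  if (!identical(x$format, "screening_tool"))
    stop("not a screening-tool file: ", path, call. = FALSE)
  if (!identical(as.integer(x$version), TOOL_SCHEMA_VERSION))
    stop("unsupported screening-tool schema version: ", x$version,
         call. = FALSE)
  if (!is.numeric(x$step1_threshold) || length(x$step1_threshold) != 1)
    stop("invalid step1_threshold in ", path, call. = FALSE)
  entries <- data.frame(
    item_id = vapply(x$scoring, `[[`, character(1), "item_id"),
    sprc = vapply(x$scoring, `[[`, numeric(1), "sprc"),
    score = vapply(x$scoring, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  scoring <- structure(list(period = x$period, entries = entries,
                            rounding_mode = match.arg(x$rounding_mode,
                                                      ROUNDING_MODES)),
                       class = "scoring_table")
  assemble_tool(scoring, x$step1_threshold,
                step2_items = unlist(x$step2$items),
                step3_items = unlist(x$step3$items),
                step3_min_count = x$step3$min_count,
                period = x$period,
                mandatory_referral_items =
                  as.character(unlist(x$mandatory_referral_items)),
                step_semantics = x$step_semantics,
                provenance = x$provenance,
                derivation_metrics = x$derivation_metrics)
}

#' Write screening results and funnel report
#'
#' @param screened output of [screen_cohort()].
#' @param results_path CSV of per-record results (optional).
#' @param funnel_path JSON of the funnel report (optional).
#' @return `screened`, invisibly.
#' @export
write_screening_output <- function(screened, results_path = NULL,
                                   funnel_path = NULL) {
  if (!is.null(results_path))
    utils::write.csv(screened$results, results_path, row.names = FALSE,
                     na = "")
  if (!is.null(funnel_path)) {
    f <- screened$funnel
    jsonlite::write_json(list(n_screened = f$n_screened, stages = f$stages,
                              n_positive = f$n_positive,
                              pct_positive = f$pct_positive),
                         funnel_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(screened)
}

# reproducibility contract: every CLI run logs seed, config hash and input
# checksums as one structured line
run_log <- function(subcommand, seed = NA, config = NULL, inputs = character()) {
  config_hash <- if (is.null(config)) NA_character_ else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
    unname(tools::md5sum(tmp))
  }
  checksums <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else NULL
  line <- jsonlite::toJSON(list(event = "run", subcommand = subcommand,
                                seed = seed, config_hash = config_hash,
                                input_md5 = checksums),
                           auto_unbox = TRUE, null = "null")
  message(line)
  invisible(line)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file of derivation / analysis settings.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
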