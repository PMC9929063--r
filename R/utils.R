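#' @keywords internal
"_PACKAGE"

# package-local cache for parsed packaged fixtures
.obscreen_cache <- new.env(parent = emptyenv())

PERIODS <- c("first_visit", "second_trimester", "third_trimester", "postpartum")

RESERVED_COLUMNS <- c("record_id", "period", "admin_cooperation",
                      "hospital_support", "epds_total")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial ("half-up") rounding for non-negative quantities. Item scores
#' and report percentages follow this convention (13.5 points round to 14,
#' 35.7\% prints as 36\%), unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector, non-negative.
#' @param digits integer number of decimal places to keep.
#' @return `x` rounded to `digits` places, halves rounded up.
#' @examples
#' round_half_up(c(13.5, 16.5, 35.714), 0)
#' round_half_up(0.212 * 100, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # guard against binary representation landing a true half a hair below .5
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a count, rounded half-up
#'
#' @param num numerator count.
#' @param den denominator count (> 0).
#' @param digits decimal places of the percentage (0 = whole percent).
#' @return `100 * num / den`, rounded half-up.
#' @examples
#' pct_half_up(5, 14)    # 36
#' pct_half_up(28, 415, digits = 1)  # 6.7
#' @export
pct_half_up <- function(num, den, digits = 0) {
  stopifnot(all(den > 0))
  round_half_up(100 * num / den, digits)
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "obscreen")
  if (!nzchar(path)) stop("packaged data file not found: ", file, call. = FALSE)
  path
}

read_packaged_json <- function(file) {
  key <- paste0("json:", file)
  if (!is.null(.obscreen_cache[[key]])) return(.obscreen_cache[[key]])
  obj <- jsonlite::read_json(extdata_path(file))
  .obscreen_cache[[key]] <- obj
  obj
}

assert_period <- function(period) {
  if (!is.character(period) || length(period) != 1L || !period %in% PERIODS)
    stop("`period` must be one of: ", paste(PERIODS, collapse = ", "),
         call. = FALSE)
  period
}

# normalization applied to answer strings before matching
normalize_answer <- function(x) tolower(trimws(x))
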