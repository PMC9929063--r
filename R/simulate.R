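#' Parameters for synthetic interview cohorts
#'
#' Assembles the generating parameters of a synthetic questionnaire cohort.
#' Defaults come from the packaged `simulation_defaults.json`: outcome
#' prevalence per period (2.5\% at the first visit, 6\% in the second
#' trimester), per-item odds ratios linking the latent need-for-support
#' outcome to each risk indicator, baseline indicator prevalences in the
#' outcome-negative stratum (approximate, not published), a cell-wise
#' missingness rate, and a logistic EPDS model (marginal P(EPDS >= 9) of
#' 6.7\% with per-item effect odds ratios).
#'
#' @param period care period of the sheet to simulate.
#' @param n cohort size (>= 1).
#' @param seed integer seed; the same parameters and seed reproduce the
#'   cohort exactly.
#' @param outcome_prevalence overrides the default outcome prevalence.
#' @param item_effects named numeric, odds ratios per item (> 0); overrides
#'   merge into the defaults.
#' @param baseline_item_prevalence named numeric in (0,1); overrides merge
#'   into the defaults.
#' @param missing_rate probability in [0,1) that any one indicator cell is
#'   masked.
#' @param epds_prevalence_ge9 target marginal P(EPDS >= 9).
#' @param epds_effect_ors named numeric odds ratios of EPDS >= 9 per item;
#'   overrides merge into the defaults.
#' @return a `simulation_params` list.
#' @examples
#' p <- simulation_params("first_visit", n = 500, seed = 1)
#' p$outcome_prevalence
#' @export
simulation_params <- function(period, n, seed = 1L,
                              outcome_prevalence = NULL,
                              item_effects = NULL,
                              baseline_item_prevalence = NULL,
                              missing_rate = NULL,
                              epds_prevalence_ge9 = NULL,
                              epds_effect_ors = NULL) {
  assert_period(period)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  d <- read_packaged_json("simulation_defaults.json")
  pd <- d$periods[[period]]
  ids <- names(pd$items)
  base <- vapply(pd$items, function(x) x$baseline, numeric(1))
  ors <- vapply(pd$items, function(x) x$or, numeric(1))
  epds_or <- vapply(pd$items, function(x) x$epds_or, numeric(1))
  names(base) <- names(ors) <- names(epds_or) <- ids
  merge_over <- function(def, over) {
    if (is.null(over)) return(def)
    bad <- setdiff(names(over), names(def))
    if (length(bad)) stop("unknown item(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    def[names(over)] <- unlist(over)
    def
  }
  base <- merge_over(base, baseline_item_prevalence)
  ors <- merge_over(ors, item_effects)
  epds_or <- merge_over(epds_or, epds_effect_ors)
  out <- list(period = period, n = as.integer(n), seed = as.integer(seed),
              outcome_prevalence = outcome_prevalence %||% pd$outcome_prevalence,
              baseline_item_prevalence = base,
              item_effects = ors,
              missing_rate = missing_rate %||% d$missing_rate,
              epds_prevalence_ge9 = epds_prevalence_ge9 %||% d$epds_prevalence_ge9,
              epds_effect_ors = epds_or)
  with(out, {
    stopifnot(outcome_prevalence >= 0, outcome_prevalence <= 1,
              all(baseline_item_prevalence > 0),
              all(baseline_item_prevalence < 1),
              all(item_effects > 0), all(epds_effect_ors > 0),
              missing_rate >= 0, missing_rate < 1,
              epds_prevalence_ge9 >= 0, epds_prevalence_ge9 <= 1)
  })
  structure(out, class = "simulation_params")
}

#' Generate a synthetic interview cohort
#'
#' Draws the need-for-support outcome Bernoulli(`outcome_prevalence`), then
#' each item indicator conditionally independently given the outcome:
#' probability `p0` (the baseline) in the outcome-negative stratum and `p1`
#' with `odds(p1) = OR * odds(p0)` in the outcome-positive stratum, so the
#' stratified 2x2 odds ratio of each item equals its generating value in
#' expectation. Deterministic given the seed.
#'
#' @param params a `simulation_params`.
#' @return a `cohort` with indicators and `admin_cooperation` filled
#'   (`epds_total` is filled separately by [generate_epds()]).
#' @examples
#' coh <- generate_cohort(simulation_params("second_trimester", 200, seed = 7))
#' nrow(coh)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n
  y <- stats::rbinom(n, 1L, params$outcome_prevalence)
  ids <- names(params$baseline_item_prevalence)
  df <- data.frame(record_id = sprintf("sim%06d", seq_len(n)),
                   period = params$period, stringsAsFactors = FALSE)
  for (id in ids) {
    p0 <- params$baseline_item_prevalence[[id]]
    p1 <- stats::plogis(stats::qlogis(p0) + log(params$item_effects[[id]]))
    p <- ifelse(y == 1L, p1, p0)
    df[[id]] <- stats::rbinom(n, 1L, p)
  }
  df$admin_cooperation <- y
  df$hospital_support <- NA_integer_
  df$epds_total <- NA_integer_
  as_cohort(df, params$period,
            provenance = sprintf("synthetic: period=%s n=%d seed=%d",
                                 params$period, n, params$seed))
}

# calibrate the intercept of a logistic model so the marginal mean response
# hits `target`, by bisection on the intercept
calibrate_intercept <- function(lp, target, tol = 1e-8) {
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("EPDS prevalence target is not attainable", call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Fill postpartum EPDS totals on a cohort
#'
#' P(EPDS >= 9) follows a logistic model in a record's risk indicators with
#' the configured per-item effect odds ratios; the intercept is calibrated by
#' bisection so the cohort-level marginal prevalence matches
#' `epds_prevalence_ge9`. The integer total is then drawn uniformly within
#' the indicated band (9-30 above threshold, 0-8 below). Missing indicators
#' contribute no effect.
#'
#' @param cohort a non-empty `cohort`.
#' @param params the `simulation_params` used (supplies effects, target
#'   prevalence and the seed; EPDS draws use a stream derived from it).
#' @return the cohort with `epds_total` filled.
#' @export
generate_epds <- function(cohort, params) {
  stopifnot(inherits(params, "simulation_params"), nrow(cohort) >= 1)
  set.seed(params$seed + 1L)
  ids <- intersect(cohort_items(cohort), names(params$epds_effect_ors))
  lp <- rep(0, nrow(cohort))
  for (id in ids) {
    x <- cohort[[id]]
    x[is.na(x)] <- 0L
    lp <- lp + x * log(params$epds_effect_ors[[id]])
  }
  target <- params$epds_prevalence_ge9
  if (target <= 0) {
    ge9 <- rep(0L, nrow(cohort))
  } else if (target >= 1) {
    ge9 <- rep(1L, nrow(cohort))
  } else {
    b0 <- calibrate_intercept(lp, target)
    ge9 <- stats::rbinom(nrow(cohort), 1L, stats::plogis(b0 + lp))
  }
  cohort$epds_total <- ifelse(ge9 == 1L,
                              sample(9:30, nrow(cohort), replace = TRUE),
                              sample(0:8, nrow(cohort), replace = TRUE))
  cohort$epds_total <- as.integer(cohort$epds_total)
  cohort
}

#' Mask indicator cells completely at random
#'
#' Each indicator cell is independently set missing with probability
#' `missing_rate` (missing completely at random); outcome and EPDS columns
#' are never masked.
#'
#' @param cohort a `cohort`.
#' @param missing_rate probability in [0, 1).
#' @param seed integer seed for the mask.
#' @return the cohort with masked cells set to `NA`.
#' @export
inject_missingness <- function(cohort, missing_rate, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (missing_rate == 0) return(cohort)
  set.seed(seed)
  for (id in cohort_items(cohort)) {
    mask <- stats::runif(nrow(cohort)) < missing_rate
    cohort[[id]][mask] <- NA_integer_
  }
  cohort
}

#' One-call synthetic cohort with EPDS and missingness
#'
#' Convenience wrapper chaining [generate_cohort()], [generate_epds()] and
#' [inject_missingness()] under one seed.
#'
#' @inheritParams generate_cohort
#' @param with_epds fill EPDS totals?
#' @param with_missing apply the configured missingness rate?
#' @return a `cohort`.
#' @export
simulate_cohort <- function(params, with_epds = TRUE, with_missing = TRUE) {
  coh <- generate_cohort(params)
  if (with_epds) coh <- generate_epds(coh, params)
  if (with_missing && params$missing_rate > 0)
    coh <- inject_missingness(coh, params$missing_rate, params$seed + 2L)
  coh
}
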