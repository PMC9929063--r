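# fixture builders and independent oracles shared across the suite

# cohort holding one binary item x and outcome y with 2x2 cell counts
# a = x1/y1, b = x0/y1, c = x1/y0, d = x0/y0
make_2x2_cohort <- function(a, b, c, d, period = "first_visit",
                            item = "maternal_mental_disorder") {
  df <- data.frame(
    record_id = sprintf("r%03d", seq_len(a + b + c + d)),
    period = period,
    stringsAsFactors = FALSE)
  df[[item]] <- rep(c(1L, 0L, 1L, 0L), c(a, b, c, d))
  df$admin_cooperation <- rep(c(1L, 1L, 0L, 0L), c(a, b, c, d))
  as_cohort(df, period, provenance = "test 2x2 fixture")
}

# exhaustive concordant-pair AUC: ties contribute one half
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Spearman by hand: Pearson correlation of mid-ranks
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))

# random indicator vector for one period's sheet (0/1/NA)
random_record <- function(period, p_risk = 0.3, p_missing = 0.1) {
  ids <- item_ids(interview_schema(period))
  v <- sample(c(0L, 1L, NA_integer_), length(ids), replace = TRUE,
              prob = c(1 - p_risk - p_missing, p_risk, p_missing))
  stats::setNames(v, ids)
}

# stage order helper: later stages are "further along" the funnel
stage_rank <- function(stage) {
  match(stage, c("negative_step1", "negative_step2", "negative_step3",
                 "positive"))
}
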