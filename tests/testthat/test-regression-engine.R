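test_that("a perfect single predictor has standardized coefficient 1", {
  df <- data.frame(record_id = as.character(1:20), period = "first_visit",
                   maternal_mental_disorder = rep(c(1L, 0L), 10))
  df$admin_cooperation <- df$maternal_mental_disorder
  coh <- as_cohort(df, "first_visit")
  fit <- suppressWarnings(  # summary.lm flags the (intended) perfect fit
    fit_linear_standardized(coh, "admin_cooperation",
                            "maternal_mental_disorder"))
  expect_equal(fit$terms$sprc, 1.0, tolerance = 1e-12)
  expect_equal(fit$n_used, 20L)
})

test_that("two-predictor standardized coefficients match the closed form", {
  set.seed(8)
  n <- 200
  x1 <- rbinom(n, 1, 0.4); x2 <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(-1 + x1 + 0.5 * x2))
  df <- data.frame(record_id = as.character(1:n), period = "first_visit",
                   depression_symptoms = x1, economic_status = x2,
                   admin_cooperation = y)
  coh <- as_cohort(df, "first_visit")
  fit <- fit_linear_standardized(coh, "admin_cooperation",
                                 c("depression_symptoms", "economic_status"))
  r_y1 <- cor(y, x1); r_y2 <- cor(y, x2); r_12 <- cor(x1, x2)
  b1 <- (r_y1 - r_y2 * r_12) / (1 - r_12^2)
  b2 <- (r_y2 - r_y1 * r_12) / (1 - r_12^2)
  expect_equal(fit$terms$sprc, c(b1, b2), tolerance = 1e-10)
})

test_that("independent outcome gives near-zero standardized coefficients", {
  set.seed(9)
  n <- 50000
  df <- data.frame(record_id = as.character(1:n), period = "first_visit",
                   depression_symptoms = rbinom(n, 1, 0.3),
                   economic_status = rbinom(n, 1, 0.2),
                   worries_older_child = rbinom(n, 1, 0.4),
                   admin_cooperation = rbinom(n, 1, 0.1))
  coh <- as_cohort(df, "first_visit")
  fit <- fit_linear_standardized(
    coh, "admin_cooperation",
    c("depression_symptoms", "economic_status", "worries_older_child"))
  expect_true(all(abs(fit$terms$sprc) < 0.02))
})

test_that("aliased predictors raise a collinearity error naming them", {
  df <- data.frame(record_id = as.character(1:40), period = "first_visit",
                   depression_symptoms = rep(c(1L, 0L), 20))
  df$economic_status <- df$depression_symptoms
  df$admin_cooperation <- rep(c(1L, 0L, 0L, 0L), 10)
  coh <- as_cohort(df, "first_visit")
  expect_error(fit_linear_standardized(
    coh, "admin_cooperation", c("depression_symptoms", "economic_status")),
    "collinear|aliased")
})

test_that("univariate logistic odds ratio equals the cross-product ratio", {
  coh <- make_2x2_cohort(20, 10, 10, 20)
  fit <- fit_logistic(coh, "admin_cooperation", "maternal_mental_disorder")
  expect_equal(fit$terms$odds_ratio, 4.0, tolerance = 1e-6)
  expect_false(fit$terms$separation)
  expect_true(fit$terms$ci_low <= 4.0 && 4.0 <= fit$terms$ci_high)

  bal <- make_2x2_cohort(10, 10, 10, 10)
  fitb <- fit_logistic(bal, "admin_cooperation", "maternal_mental_disorder")
  expect_equal(fitb$terms$odds_ratio, 1.0, tolerance = 1e-6)
})

test_that("complete separation is flagged per term, not fatal", {
  # no exposed cases among outcome-positives: the estimate diverges
  coh <- make_2x2_cohort(0, 30, 5, 25)
  fit <- fit_logistic(coh, "admin_cooperation", "maternal_mental_disorder")
  expect_true(fit$terms$separation)
  expect_true(is.na(fit$terms$ci_low))
})

test_that("variance inflation factors follow 1/(1 - R squared)", {
  set.seed(10)
  n <- 50000
  df <- data.frame(a = rbinom(n, 1, 0.3), b = rbinom(n, 1, 0.4))
  v <- vif(df, c("a", "b"))
  expect_true(all(v >= 1))
  expect_true(all(abs(v - 1) < 0.02))

  # engineered sample correlation of exactly 0.8 -> VIF 1/(1-0.64)
  u <- as.numeric(scale(1:4))
  e <- c(1, -1, -1, 1); e <- e / sqrt(sum(e^2) / 3)
  df2 <- data.frame(x = u, y = 0.8 * u + 0.6 * e)
  expect_equal(cor(df2$x, df2$y), 0.8, tolerance = 1e-12)
  v2 <- vif(df2, c("x", "y"))
  expect_equal(unname(v2), rep(1 / (1 - 0.64), 2), tolerance = 1e-10)

  df3 <- data.frame(a = df$a, dup = df$a)
  expect_true(all(is.infinite(vif(df3, c("a", "dup")))))
})

test_that("Spearman correlation matches the rank-Pearson oracle", {
  expect_equal(spearman_rho(1:5, 1:5), 1.0)
  expect_equal(spearman_rho(1:5, 5:1), -1.0)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(spearman_rho(1:2, 1:2), "length")
  set.seed(12)
  for (i in 1:25) {
    x <- sample(0:3, 30, replace = TRUE)
    y <- sample(0:3, 30, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("ROC operating points and AUC behave on canonical cases", {
  r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  r2 <- roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r2$auc, 0.75)
  r3 <- roc_curve(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(r3$auc, 0.5)
  expect_error(roc_curve(1:4, rep(1, 4)), "both label classes")
  # sensitivity is non-increasing in the threshold
  expect_true(all(diff(r2$points$sensitivity) <= 0))
  expect_true(all(r2$points$specificity >= 0 & r2$points$specificity <= 1))
})

test_that("AUC equals the exhaustive concordant-pair fraction", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    scores <- sample(0:20, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_curve(scores, labels)$auc,
                 auc_bruteforce(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- round(runif(80, 0, 40), 1)
  labels <- rbinom(80, 1, 0.3)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
  expect_equal(roc_curve(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("Youden cutoff selection matches brute-force enumeration", {
  r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  cut <- select_cutoff(r)
  expect_equal(cut$sensitivity, 1.0)
  expect_equal(cut$specificity, 1.0)
  expect_gt(cut$threshold, 2); expect_lte(cut$threshold, 3)

  scores <- c(1, 2, 3, 4); labels <- c(0, 1, 0, 1)
  r2 <- roc_curve(scores, labels)
  best_j <- -Inf; best_t <- NA
  for (t in sort(unique(scores))) {  # enumeration oracle, low ties first
    j <- mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
    if (j > best_j) { best_j <- j; best_t <- t }
  }
  cut2 <- select_cutoff(r2)
  expect_equal(cut2$threshold, best_t)
  expect_equal(cut2$sensitivity + cut2$specificity - 1, best_j)

  # useless classifier: Youden 0 everywhere, lowest threshold returned
  r3 <- roc_curve(rep(5, 8), rep(c(0, 1), 4))
  cut3 <- select_cutoff(r3)
  expect_equal(cut3$youden, 0)
  expect_equal(cut3$threshold, 5)
})
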