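#' ROC curve of a score against a binary label
#'
#' Operating points are taken at every distinct score value `t` with the
#' screening convention "positive iff score >= t": sensitivity is the
#' fraction of labelled positives at or above `t`, specificity the fraction
#' of negatives below `t`. A final `Inf` threshold closes the curve at
#' (sensitivity 0, specificity 1). The AUC is the Mann-Whitney rank
#' statistic — the probability a random positive outscores a random
#' negative, ties counting one half — which equals the trapezoidal area.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length; both classes must occur.
#' @return an object of class `roc_screening`: list with `points` (data
#'   frame `threshold`, `sensitivity`, `specificity`) and `auc`.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc  # 0.75
#' @export
roc_curve <- function(scores, labels) {
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  stopifnot(all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both label classes must be present", call. = FALSE)
  thr <- c(sort(unique(scores)), Inf)
  pts <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[labels == 1] >= t),
                         numeric(1)),
    specificity = vapply(thr, function(t) mean(scores[labels == 0] < t),
                         numeric(1)))
  r <- rank(scores)  # mid-ranks: ties contribute 1/2 concordance
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(points = pts, auc = auc), class = "roc_screening")
}

#' @export
print.roc_screening <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "operating points, AUC =",
      format(x$auc, digits = 3), "\n")
  invisible(x)
}

#' Select an ROC cutoff
#'
#' Chooses the operating threshold maximizing the Youden index
#' (sensitivity + specificity - 1). Ties are broken toward the lower
#' threshold, i.e. the more sensitive screen.
#'
#' @param curve a `roc_screening`.
#' @param criterion currently only `"youden"`.
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`,
#'   `auc`.
#' @examples
#' select_cutoff(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1)))
#' @export
select_cutoff <- function(curve, criterion = c("youden")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(curve, "roc_screening"))
  pts <- curve$points[is.finite(curve$points$threshold), , drop = FALSE]
  if (nrow(pts) == 0) stop("degenerate ROC curve", call. = FALSE)
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j == max(j))[1]  # points ordered by increasing threshold
  list(threshold = pts$threshold[best],
       sensitivity = pts$sensitivity[best],
       specificity = pts$specificity[best],
       youden = j[best],
       auc = curve$auc)
}
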