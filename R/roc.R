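check_two_classes <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be logical with no missing values")
  if (!any(labels) || all(labels))
    stop("both classes must be present (labels are all ",
         if (all(labels)) "positive" else "negative", ")")
  labels
}

#' Tie-corrected rank AUC
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, counting ties as 1/2 (the Mann-Whitney form). This is the
#' unambiguous definition when scores take few distinct values, as they do
#' for two-item instruments (at most 16 distinct probabilities, or 7 distinct
#' sum scores), and equals the trapezoidal area under the ROC polygon over
#' the distinct score thresholds.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Logical (or 0/1) reference-standard labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- check_two_classes(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Grouped-data rank AUC: scores take few distinct values with per-class
# counts. Used by the pipeline where data are pre-aggregated into patterns.
auc_grouped <- function(scores, pos_counts, neg_counts) {
  P <- sum(pos_counts); N <- sum(neg_counts)
  if (P == 0 || N == 0)
    stop("both classes must be present to compute an AUC")
  o <- order(scores)
  pos <- pos_counts[o]; neg <- neg_counts[o]
  neg_below <- cumsum(neg) - neg
  sum(pos * (neg_below + neg / 2)) / (P * N)
}

#' Exact operating points of a score-threshold rule family
#'
#' For each threshold `t`, classifies positive iff `score >= t` and tallies
#' the exact confusion counts, sensitivity, specificity, Youden index
#' (sensitivity + specificity - 1), and count-based PPV/NPV (flagged `NaN`
#' when their denominator is empty, never silently zero).
#'
#' @param scores Numeric scores.
#' @param labels Logical reference-standard labels; both classes required.
#' @param thresholds Thresholds to evaluate; default: the distinct scores in
#'   descending order (every achievable non-trivial rule).
#' @return Data frame of class `operating_points`, one row per threshold:
#'   `threshold`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `youden`, `ppv`, `npv`.
#' @export
operating_points <- function(scores, labels, thresholds = NULL) {
  labels <- check_two_classes(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  if (is.null(thresholds))
    thresholds <- sort(unique(scores), decreasing = TRUE)
  rows <- lapply(thresholds, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
    data.frame(threshold = t, tp = tp, fp = fp, tn = tn, fn = fn)
  })
  out <- do.call(rbind, rows)
  out$sensitivity <- out$tp / (out$tp + out$fn)
  out$specificity <- out$tn / (out$tn + out$fp)
  out$youden <- out$sensitivity + out$specificity - 1
  out$ppv <- ifelse(out$tp + out$fp > 0, out$tp / (out$tp + out$fp), NaN)
  out$npv <- ifelse(out$tn + out$fn > 0, out$tn / (out$tn + out$fn), NaN)
  class(out) <- c("operating_points", "data.frame")
  out
}

#' ROC curve over all achievable thresholds
#'
#' Operating points at every distinct score (descending) plus the closing
#' all-negative rule, together with the tie-corrected rank AUC.
#'
#' @inheritParams operating_points
#' @return Object of class `roc_curve`: list with `points`
#'   (an [operating_points()] frame anchored at sensitivity 1/specificity 0
#'   and closed at sensitivity 0/specificity 1) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  # ascending thresholds run from the all-positive rule (threshold = min
  # score) to an appended all-negative rule, closing the curve
  thr <- c(sort(unique(scores)), max(scores) + 1)
  pts <- operating_points(scores, labels, thresholds = thr)
  structure(list(points = pts, auc = auc_rank(scores, labels)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  fpr <- 1 - x$points$specificity
  tpr <- x$points$sensitivity
  o <- order(fpr, tpr)
  if (!add) {
    graphics::plot(fpr[o], tpr[o], type = "b", pch = 19, col = col,
                   xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(fpr[o], tpr[o], type = "b", pch = 19, col = col, ...)
  }
  invisible(x)
}

#' Select the operating point with maximal Youden index
#'
#' Ties are broken toward higher sensitivity (i.e. the lower threshold):
#' prescreening is a rule-out application, so when two rules balance errors
#' equally the more sensitive one is preferred. Remaining ties resolve to
#' the lower threshold.
#'
#' @param points An [operating_points()] frame (or compatible data frame).
#' @return The selected row.
#' @export
select_youden <- function(points) {
  if (!nrow(points)) stop("cannot select from an empty operating-point list")
  o <- order(-points$youden, -points$sensitivity, points$threshold)
  points[o[1], , drop = FALSE]
}

#' Prevalence-based predictive values
#'
#' PPV and NPV from sensitivity, specificity and prevalence by Bayes'
#' theorem: `ppv = sens*p / (sens*p + (1-spec)*(1-p))` and
#' `npv = spec*(1-p) / (spec*(1-p) + (1-sens)*p)`. Undefined values (zero
#' denominator) are returned as `NaN`.
#'
#' @param sensitivity,specificity Proportions in \[0, 1\].
#' @param prevalence Prevalence in (0, 1).
#' @return Named list with `ppv` and `npv`.
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly between 0 and 1")
  dp <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  dn <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  list(ppv = if (dp > 0) sensitivity * prevalence / dp else NaN,
       npv = if (dn > 0) specificity * (1 - prevalence) / dn else NaN)
}

#' Operating points of the sum-score cutoff family
#'
#' The conventional psychometric rule family for an item subset: classify
#' positive iff the unweighted subscore meets an integer cutoff `c`, for
#' every cutoff `c` in `0 .. 3*|items|`. For two items this is exactly 7
#' rules (subscores 0-6), the family the PHQ-2 cutoffs of 2 and 3 belong to.
#'
#' @param data Labelled dataset.
#' @param items Nonempty integer vector of item indices in 1..9.
#' @return An [operating_points()] frame, one row per cutoff, ascending.
#' @export
sum_score_points <- function(data, items) {
  items <- as.integer(items)
  if (!length(items) || any(items < 1L | items > 9L) || anyDuplicated(items))
    stop("items must be a nonempty set of distinct indices in 1..9")
  check_labeled(data)
  scores <- rowSums(data[, paste0("item", items), drop = FALSE])
  operating_points(scores, data$label, thresholds = 0:(3L * length(items)))
}
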