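# Classifier evaluation: Mann-Whitney AUC, thresholded confusion summaries
# with exact binomial confidence intervals, one-vs-rest multiclass metrics,
# probability-bin calibration, and the three-way questionnaire / cotinine /
# CpG-model concordance partition.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a randomly
#' chosen positive outscores a randomly chosen negative, with ties credited
#' one half. Implemented through mid-ranks, which is exactly equivalent to
#' pair counting.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical, 0/1, or two-level factor).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (anyNA(labels)) stop("labels must be binary with no missing values")
  labels
}

#' Confusion summary at a probability threshold
#'
#' Calls positive strictly above the threshold, and reports sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), accuracy with an exact
#' (Clopper-Pearson) binomial 95% confidence interval, and the AUC of the
#' underlying probabilities. Metrics with an empty denominator (e.g.
#' sensitivity with no positives) are returned as `NaN` and flagged in
#' `undefined`.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param labels Binary labels.
#' @param threshold Positive call when `prob > threshold` (default 0.5).
#' @return List of class `classification_report`: `threshold`, `n`, `tp`,
#'   `fp`, `tn`, `fn`, `accuracy`, `ci_lower`, `ci_upper`, `sensitivity`,
#'   `specificity`, `auc`, `undefined`.
#' @export
confusion_at <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0) stop("empty input")
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  labels <- as_binary(labels)
  call_pos <- probs > threshold
  tp <- sum(call_pos & labels == 1)
  fp <- sum(call_pos & labels == 0)
  tn <- sum(!call_pos & labels == 0)
  fn <- sum(!call_pos & labels == 1)
  n <- length(labels)
  acc <- (tp + tn) / n
  ci <- clopper_pearson(tp + tn, n)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spec <- if (tn + fp > 0) tn / (tn + fp) else NaN
  auc <- if (length(unique(labels)) == 2) roc_auc(probs, labels) else NaN
  structure(
    list(threshold = threshold, n = n, tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = acc, ci_lower = ci[1], ci_upper = ci[2],
         sensitivity = sens, specificity = spec, auc = auc,
         undefined = c(sensitivity = is.nan(sens),
                       specificity = is.nan(spec), auc = is.nan(auc))),
    class = "classification_report"
  )
}

clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "n = %d @ threshold %.4g\naccuracy %.3f (95%% CI %.3f-%.3f)\nsensitivity %.3f  specificity %.3f  AUC %.3f\n",
    x$n, x$threshold, x$accuracy, x$ci_lower, x$ci_upper,
    x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' One-vs-rest multiclass report
#'
#' Predicted category is the row argmax of the probability matrix; for each
#' category the one-vs-rest sensitivity and specificity come from the argmax
#' confusion and the one-vs-rest AUC from that category's probability
#' column.
#'
#' @param prob_matrix Samples x K probability matrix with category column
#'   names; rows must sum to 1 (tolerance 1e-8).
#' @param labels Category labels; every column's category must be allowed,
#'   and a category absent from `labels` is an error.
#' @return Data frame with one row per category: `category`, `n`,
#'   `sensitivity`, `specificity`, `auc`.
#' @export
multiclass_report <- function(prob_matrix, labels) {
  prob_matrix <- as.matrix(prob_matrix)
  if (is.null(colnames(prob_matrix))) stop("prob_matrix needs column names")
  if (any(abs(rowSums(prob_matrix) - 1) > 1e-8)) {
    stop("probability rows must sum to 1")
  }
  labels <- as.character(labels)
  cats <- colnames(prob_matrix)
  if (!all(cats %in% labels)) {
    stop("category absent from labels: ",
         paste(setdiff(cats, labels), collapse = ", "))
  }
  pred <- cats[max.col(prob_matrix, ties.method = "first")]
  rows <- lapply(cats, function(k) {
    is_k <- labels == k
    call_k <- pred == k
    data.frame(
      category = k, n = sum(is_k),
      sensitivity = sum(call_k & is_k) / sum(is_k),
      specificity = sum(!call_k & !is_k) / sum(!is_k),
      auc = roc_auc(prob_matrix[, k], is_k),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Probability-bin calibration of a binary classifier
#'
#' Splits `[0, 1]` into equal-width bins and reports, per bin, the count and
#' the fraction of participants whose 0.5-thresholded call was correct (the
#' overlay of the probability-histogram figure). Empty bins report count 0
#' and `NaN` accuracy.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels.
#' @param n_bins Number of bins (at least 2).
#' @param threshold Call threshold used to judge correctness.
#' @return Data frame: `bin`, `lower`, `upper`, `count`, `accuracy`.
#' @export
calibration_bins <- function(probs, labels, n_bins = 10, threshold = 0.5) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  labels <- as_binary(labels)
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- cut(probs, edges, include.lowest = TRUE, labels = FALSE)
  correct <- (probs > threshold) == (labels == 1)
  rows <- lapply(seq_len(n_bins), function(b) {
    in_b <- idx == b
    data.frame(bin = b, lower = edges[b], upper = edges[b + 1],
               count = sum(in_b),
               accuracy = if (any(in_b)) mean(correct[in_b]) else NaN)
  })
  do.call(rbind, rows)
}

#' Three-way smoker-call concordance partition
#'
#' Cross-tabulates smoker calls from the questionnaire, the cotinine cut-off
#' and the CpG model into the 8 cells of the agreement partition, and
#' derives each biomarker method's sensitivity/specificity against the
#' questionnaire reference.
#'
#' @param questionnaire_calls,cotinine_calls,cpg_calls Equal-length binary
#'   vectors (1 = called smoker).
#' @return List of class `concordance_partition` with `cells` (data frame of
#'   the 8 cells, columns `questionnaire`, `cotinine`, `cpg`, `n`), `n`, and
#'   `summary` (per-method sensitivity/specificity vs questionnaire plus
#'   cross-method smoker-call overlap fractions).
#' @export
concordance_partition <- function(questionnaire_calls, cotinine_calls,
                                  cpg_calls) {
  q <- as_binary(questionnaire_calls)
  co <- as_binary(cotinine_calls)
  m <- as_binary(cpg_calls)
  if (length(q) != length(co) || length(q) != length(m)) {
    stop("call vectors must have equal length")
  }
  grid <- expand.grid(questionnaire = c(0L, 1L), cotinine = c(0L, 1L),
                      cpg = c(0L, 1L))
  grid$n <- mapply(function(a, b, d) sum(q == a & co == b & m == d),
                   grid$questionnaire, grid$cotinine, grid$cpg)
  cpg_true_pos <- sum(m == 1 & q == 1)
  cot_true_pos <- sum(co == 1 & q == 1)
  both_true_pos <- sum(m == 1 & co == 1 & q == 1)
  summary <- list(
    cpg = list(sensitivity = mean(m[q == 1] == 1),
               specificity = mean(m[q == 0] == 0)),
    cotinine = list(sensitivity = mean(co[q == 1] == 1),
                    specificity = mean(co[q == 0] == 0)),
    # of the smokers each method got right, the fraction the other also got
    overlap_cpg_in_cotinine = if (cpg_true_pos > 0)
      both_true_pos / cpg_true_pos else NaN,
    overlap_cotinine_in_cpg = if (cot_true_pos > 0)
      both_true_pos / cot_true_pos else NaN
  )
  structure(list(cells = grid, n = length(q), summary = summary),
            class = "concordance_partition")
}

#' @export
print.concordance_partition <- function(x, ...) {
  cat(sprintf("Three-way concordance over %d participants\n", x$n))
  print(x$cells, row.names = FALSE)
  invisible(x)
}
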