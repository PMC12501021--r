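# Confusion-matrix construction, one-vs-rest class metrics, macro
# aggregation, ROC-AUC and McNemar's paired test.

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes; exact integer pair
#' counts.
#'
#' @param y_true,y_pred Integer labels in `0..K-1` (or factors/characters
#'   sharing the levels in `labels`).
#' @param k Number of classes.
#' @param labels Optional class names (length `k`).
#' @return `k x k` integer matrix with dimnames `true` x `pred`.
#' @export
confusion_matrix <- function(y_true, y_pred, k, labels = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.numeric(y_true)) {
    if (any(y_true < 0 | y_true >= k) || any(y_pred < 0 | y_pred >= k))
      stop("labels out of range 0..K-1")
    ti <- y_true + 1L; pi <- y_pred + 1L
  } else {
    if (is.null(labels)) labels <- sort(unique(c(as.character(y_true), as.character(y_pred))))
    ti <- match(as.character(y_true), labels)
    pi <- match(as.character(y_pred), labels)
    if (anyNA(ti) || anyNA(pi)) stop("labels outside the class set")
  }
  cm <- matrix(0L, k, k)
  for (i in seq_along(ti)) cm[ti[i], pi[i]] <- cm[ti[i], pi[i]] + 1L
  if (is.null(labels)) labels <- as.character(0:(k - 1))
  dimnames(cm) <- list(true = labels, pred = labels)
  cm
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class: TP (diagonal cell), FP (column rest), FN (row rest),
#' TN (remainder); precision = TP/(TP+FP), one-vs-rest accuracy =
#' (TP+TN)/n, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), all in
#' percent. `class_accuracy` is the per-class recall (diagonal over row
#' total), the quantity reported per class in confusion-matrix readings;
#' it coincides with sensitivity and is exposed under both names because
#' the one-vs-rest accuracy answers a different question. Zero
#' denominators yield `NaN`, not errors.
#'
#' @param cm Confusion matrix (rows true, columns predicted).
#' @return data.frame with one row per class.
#' @export
class_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0L) stop("empty confusion matrix")
  n <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  pct <- function(num, den) ifelse(den > 0, num / den * 100, NaN)
  data.frame(
    class = rownames(cm) %||% as.character(seq_len(nrow(cm)) - 1L),
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = pct(tp, tp + fp),
    ovr_accuracy = pct(tp + tn, n),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    class_accuracy = pct(tp, rowSums(cm)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Macro (unweighted) mean of per-class values
#'
#' The arithmetic mean across classes, rounded to two decimals for
#' reporting - the convention used in per-class metric tables' "Overall"
#' rows.
#'
#' @param values Numeric per-class values.
#' @param digits Rounding digits (default 2).
#' @return Scalar.
#' @export
macro_overall <- function(values, digits = 2) {
  if (!length(values)) stop("need at least one class")
  round(mean(values), digits)
}

#' Micro (overall multiclass) accuracy
#' @param cm Confusion matrix.
#' @return Percentage trace(cm)/n * 100.
#' @export
micro_accuracy <- function(cm) sum(diag(as.matrix(cm))) / sum(cm) * 100

#' ROC-AUC (binary)
#'
#' The probability that a random positive outscores a random negative,
#' with ties counted 1/2 - computed by the rank (Mann-Whitney)
#' formulation, which equals the trapezoidal area under the ROC curve.
#'
#' @param labels Binary labels (0/1 or logical).
#' @param scores Numeric scores (higher = more positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest multiclass AUC
#'
#' @param y_true Integer labels 0..K-1.
#' @param scores n x K score matrix (class k scores in column k+1).
#' @return Named per-class AUC vector.
#' @export
multiclass_auc <- function(y_true, scores) {
  K <- ncol(scores)
  vapply(seq_len(K), function(k) roc_auc(y_true == (k - 1), scores[, k]), 0)
}

#' Literal true-positive-rate / false-positive-rate ratio
#'
#' Exposed for completeness alongside [roc_auc()]; this ratio is not an
#' area under any curve and is reported separately.
#'
#' @param tp,fp,fn,tn One-vs-rest counts.
#' @return TPR / FPR (Inf when FPR is 0).
#' @export
tpr_fpr_ratio <- function(tp, fp, fn, tn) {
  tpr <- tp / (tp + fn)
  fpr <- fp / (fp + tn)
  tpr / fpr
}

#' Paired predictions for two classifiers
#'
#' @param correct_a,correct_b Logical vectors: per-sample correctness of
#'   models A and B on the same samples.
#' @return List of class `paired_predictions` with discordant counts `b`
#'   (A right, B wrong) and `c` (A wrong, B right) and `n`.
#' @export
paired_predictions <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  structure(list(b = sum(correct_a & !correct_b),
                 c = sum(!correct_a & correct_b),
                 n = length(correct_a)), class = "paired_predictions")
}

#' McNemar's test for paired classifiers
#'
#' Tests whether two classifiers evaluated on the same samples differ in
#' their pattern of correct/incorrect predictions, using the discordant
#' counts b and c. For `b + c < 25` the exact two-sided binomial test is
#' used; otherwise the continuity-corrected chi-squared statistic
#' `(max(|b - c| - 1, 0))^2 / (b + c)` on 1 df.
#'
#' @param x A `paired_predictions` object, or the discordant count `b`.
#' @param c_count Discordant count `c` (when `x` is given as `b`).
#' @param method `"auto"` (exact binomial when `b + c < exact_below`,
#'   chi-squared otherwise), `"chisq"` or `"exact"`.
#' @param exact_below `b + c` threshold for the automatic exact variant.
#' @return List with `b`, `c`, `statistic` (the corrected chi-squared
#'   statistic, always reported), `p_value` and `method`.
#' @export
mcnemar_test <- function(x, c_count = NULL, method = c("auto", "chisq", "exact"),
                         exact_below = 25L) {
  method <- match.arg(method)
  if (inherits(x, "paired_predictions")) {
    b <- x$b; cc <- x$c
  } else {
    b <- x; cc <- c_count
  }
  stopifnot(b >= 0, cc >= 0)
  if (b + cc == 0) stop("no discordant pairs: McNemar's test undefined")
  stat <- (max(abs(b - cc) - 1, 0))^2 / (b + cc)
  use_exact <- method == "exact" || (method == "auto" && b + cc < exact_below)
  if (use_exact) {
    p <- min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
    list(b = b, c = cc, statistic = stat, p_value = p,
         method = "exact binomial (two-sided)")
  } else {
    list(b = b, c = cc, statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         method = "continuity-corrected chi-squared")
  }
}

#' Two-proportion comparison
#'
#' Chi-squared (continuity-corrected) comparison of two independent
#' proportions, via [stats::prop.test()]; a companion to McNemar's test
#' for rate-style metrics where the pairing is unknown.
#'
#' @param x1,n1 Successes and trials for group 1.
#' @param x2,n2 Successes and trials for group 2.
#' @return List with `p1`, `p2`, `p_value`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  pt <- stats::prop.test(c(x1, x2), c(n1, n2))
  list(p1 = x1 / n1, p2 = x2 / n2, p_value = pt$p.value)
}

#' Evaluate a predictions table
#'
#' @param preds data.frame with columns `true_label`, `pred_label`
#'   (integers 0..K-1) and optionally K score columns `score_0..score_{K-1}`.
#' @param k Number of classes.
#' @param labels Optional class names.
#' @return List: `confusion` matrix, `per_class` metrics (with AUC when
#'   scores are present), `overall` (macro means + micro accuracy).
#' @export
evaluate_predictions <- function(preds, k = 7L, labels = lesion_classes) {
  cm <- confusion_matrix(preds$true_label, preds$pred_label, k, labels)
  per <- class_metrics(cm)
  score_cols <- paste0("score_", 0:(k - 1))
  if (all(score_cols %in% names(preds))) {
    per$auc <- multiclass_auc(preds$true_label, as.matrix(preds[score_cols])) * 100
  }
  overall <- list(
    macro_precision = macro_overall(per$precision),
    macro_sensitivity = macro_overall(per$sensitivity),
    macro_specificity = macro_overall(per$specificity),
    micro_accuracy = micro_accuracy(cm))
  if (!is.null(per$auc)) overall$macro_auc <- macro_overall(per$auc)
  list(confusion = cm, per_class = per, overall = overall)
}
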