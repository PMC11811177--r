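# Evaluation utilities: mask-overlap metrics, confusion-table
# classification metrics, rank-based AUC, and one-way ANOVA.

#' Jaccard index of two binary masks
#'
#' `|A n B| / |A u B|`; defined as 1 when both masks are empty (perfect
#' agreement rather than 0/0).
#'
#' @param a,b Logical matrices (or vectors) of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop_input("masks must have identical shape",
               class = "boclahe_argument_error")
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Dice coefficient of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' Satisfies `dice = 2 J / (1 + J)` with `J` the Jaccard index.
#'
#' @inheritParams jaccard
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop_input("masks must have identical shape",
               class = "boclahe_argument_error")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Classification metrics from a confusion table
#'
#' Rows are true classes, columns predicted classes. Per-class precision
#' (or recall) with an empty denominator is 0, as is F1 when
#' `precision + recall = 0`; macro averages are unweighted class means.
#'
#' @param table Square numeric matrix of non-negative counts.
#' @return List with `accuracy`, per-class `precision`, `recall`, `f1`,
#'   and `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
classification_metrics <- function(table) {
  tb <- as.matrix(table)
  if (nrow(tb) != ncol(tb) || any(tb < 0) || anyNA(tb))
    stop_input("table must be a square matrix of non-negative counts",
               class = "boclahe_argument_error")
  total <- sum(tb)
  if (total == 0)
    stop_input("empty confusion table", class = "boclahe_argument_error")
  tp <- diag(tb)
  pred <- colSums(tb)
  truth <- rowSums(tb)
  precision <- ifelse(pred > 0, tp / pred, 0)
  recall <- ifelse(truth > 0, tp / truth, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  labels <- rownames(tb) %||% as.character(seq_len(nrow(tb)))
  names(precision) <- names(recall) <- names(f1) <- labels
  list(accuracy = sum(tp) / total,
       precision = precision, recall = recall, f1 = f1,
       macro_precision = mean(precision), macro_recall = mean(recall),
       macro_f1 = mean(f1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under the ROC curve (rank formulation)
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half; invariant to strictly monotone score transforms.
#'
#' @param labels Binary vector (0/1 or logical).
#' @param scores Numeric vector, larger = more positive.
#' @return Scalar in `[0, 1]`.
#' @export
auc_roc <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores))
    stop_input("labels and scores must have the same length",
               class = "boclahe_argument_error")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop_input("both classes must be present",
               class = "boclahe_argument_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-way analysis of variance
#'
#' `F = (between-group SS / df1) / (within-group SS / df2)` with the upper
#' tail of the F distribution for the p value.
#'
#' @param groups Named list of numeric vectors, at least 2 groups with at
#'   least 2 values each.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_input("need at least 2 groups", class = "boclahe_argument_error")
  if (any(vapply(groups, length, 1L) < 2L))
    stop_input("each group needs at least 2 values",
               class = "boclahe_argument_error")
  all_v <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  n <- length(all_v)
  grand <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1L
  df2 <- n - k
  if (ss_within == 0)
    stop_input("zero within-group variance", class = "boclahe_degenerate_error")
  Fstat <- (ss_between / df1) / (ss_within / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}
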