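#' Confusion counts for binary predictions
#'
#' Tallies true/false positives and negatives, with class 1 as the positive
#' class. The four counts partition the evaluated samples.
#'
#' @param y_true Vector of observed labels, coercible to 0/1.
#' @param y_pred Vector of predicted labels, coercible to 0/1.
#' @return An object of class `"confusion_counts"`: a list with integer
#'   components `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- check_binary(y_true, "y_true")
  y_pred <- check_binary(y_pred, "y_pred")
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (length(y_true) < 1L)
    stop("need at least one sample", call. = FALSE)
  out <- list(
    tp = sum(y_true == 1L & y_pred == 1L),
    tn = sum(y_true == 0L & y_pred == 0L),
    fp = sum(y_true == 0L & y_pred == 1L),
    fn = sum(y_true == 1L & y_pred == 0L)
  )
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts (positive class = 1)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("1", "0"), predicted = c("1", "0")))
  print(m)
  invisible(x)
}

check_binary <- function(x, name) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) x <- as.integer(x)
  x <- suppressWarnings(as.numeric(x))
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop(sprintf("%s must contain only 0/1 labels", name), call. = FALSE)
  as.integer(x)
}

check_counts <- function(counts) {
  if (!inherits(counts, "confusion_counts"))
    stop("expected a 'confusion_counts' object", call. = FALSE)
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total <= 0L) stop("confusion counts are empty", call. = FALSE)
  total
}

# 0/0 denominators return 0 with a warning so that model selection stays
# well-defined for degenerate classifiers (e.g. never predicts positive).
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (0/0); returning 0", what), call. = FALSE)
    return(0)
  }
  num / den
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Standard binary classification metrics: accuracy is the fraction of correct
#' predictions, precision the fraction of predicted positives that are true
#' positives, recall the fraction of actual positives recovered, and F1 the
#' harmonic mean of precision and recall. Any 0/0 denominator returns 0 with a
#' warning.
#'
#' @param counts A `"confusion_counts"` object.
#' @return A single proportion in \[0, 1\].
#' @examples
#' cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' accuracy(cc)   # 0.5
#' f1_score(cc)   # 0.5
#' @export
accuracy <- function(counts) {
  total <- check_counts(counts)
  (counts$tp + counts$tn) / total
}

#' @rdname accuracy
#' @export
precision <- function(counts) {
  check_counts(counts)
  safe_ratio(counts$tp, counts$tp + counts$fp, "precision")
}

#' @rdname accuracy
#' @export
recall <- function(counts) {
  check_counts(counts)
  safe_ratio(counts$tp, counts$tp + counts$fn, "recall")
}

#' @rdname accuracy
#' @export
f1_score <- function(counts) {
  check_counts(counts)
  p <- suppressWarnings(precision(counts))
  r <- suppressWarnings(recall(counts))
  safe_ratio(2 * p * r, p + r, "F1")
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' Computes AUC as the probability that a randomly chosen positive sample
#' receives a higher score than a randomly chosen negative sample, counting
#' ties as 1/2. Midranks make this exact under ties, where trapezoidal
#' integration of an empirical ROC curve and the rank formulation agree
#' anyway on tie-free data.
#'
#' @param y_true Vector of observed 0/1 labels containing both classes.
#' @param scores Numeric vector of scores or positive-class probabilities.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6))  # 0.75
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- check_binary(y_true, "y_true")
  scores <- as.numeric(scores)
  if (length(y_true) != length(scores))
    stop("y_true and scores must have equal length", call. = FALSE)
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("roc_auc requires at least one positive and one negative sample",
         call. = FALSE)
  r <- rank(scores, ties.method = "average")
  u <- sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Empirical ROC coordinates at every distinct score threshold, suitable for
#' plotting or export.
#'
#' @inheritParams roc_auc
#' @return A data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   the most permissive threshold to the strictest.
#' @export
roc_points <- function(y_true, scores) {
  y_true <- check_binary(y_true, "y_true")
  scores <- as.numeric(scores)
  if (length(y_true) != length(scores))
    stop("y_true and scores must have equal length", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  keep <- !duplicated(s, fromLast = TRUE)  # one point per distinct threshold
  data.frame(
    threshold = c(Inf, s[keep]),
    fpr = c(0, fp[keep] / max(sum(y == 0L), 1L)),
    tpr = c(0, tp[keep] / max(sum(y == 1L), 1L))
  )
}

#' Full evaluation report for a binary classifier
#'
#' Bundles accuracy, precision, recall, F1 and AUC together with the
#' confusion counts they derive from.
#'
#' @param y_true Observed 0/1 labels.
#' @param y_pred Predicted 0/1 labels.
#' @param scores Optional scores/probabilities for AUC; when omitted, AUC is
#'   computed from the hard labels.
#' @param model Optional model name carried into printed/exported output.
#' @return An object of class `"metrics_report"`.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL, model = NA_character_) {
  counts <- confusion_counts(y_true, y_pred)
  if (is.null(scores)) scores <- as.numeric(check_binary(y_pred, "y_pred"))
  structure(list(
    model = model,
    accuracy = accuracy(counts),
    precision = precision(counts),
    recall = recall(counts),
    f1 = f1_score(counts),
    auc = roc_auc(y_true, scores),
    counts = counts
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  if (!is.na(x$model)) cat("Model:", x$model, "\n")
  v <- c(Accuracy = x$accuracy, Precision = x$precision,
         Recall = x$recall, F1 = x$f1, AUC = x$auc)
  print(round(v, digits))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(Model = x$model, Accuracy = x$accuracy, Precision = x$precision,
             Recall = x$recall, F1 = x$f1, AUC = x$auc,
             stringsAsFactors = FALSE)
}
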