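#' Agreement table between two classifiers
#'
#' Cross-tabulates per-sample correctness of two classifiers against the
#' truth: `n11` counts samples both predict correctly, `n00` samples both get
#' wrong, `n10` samples only the first gets right, and `n01` samples only the
#' second gets right.
#'
#' @param y_true Observed 0/1 labels.
#' @param pred_i,pred_k Predicted 0/1 labels of the two classifiers.
#' @return An object of class `"agreement_table"`: a list with integer
#'   components `n11`, `n10`, `n01`, `n00`.
#' @export
agreement_table <- function(y_true, pred_i, pred_k) {
  y_true <- check_binary(y_true, "y_true")
  pred_i <- check_binary(pred_i, "pred_i")
  pred_k <- check_binary(pred_k, "pred_k")
  n <- length(y_true)
  if (length(pred_i) != n || length(pred_k) != n)
    stop("all three vectors must have equal length", call. = FALSE)
  ci <- pred_i == y_true
  ck <- pred_k == y_true
  structure(list(
    n11 = sum(ci & ck),
    n10 = sum(ci & !ck),
    n01 = sum(!ci & ck),
    n00 = sum(!ci & !ck)
  ), class = "agreement_table")
}

#' Pairwise Q-statistic of classifier diversity
#'
#' The Q-statistic measures dependence between the correctness patterns of two
#' classifiers: `(n11*n00 - n01*n10) / (n11*n00 + n01*n10)`. It lies in
#' \[-1, 1\]; values near 0 indicate diverse (independent-looking) errors,
#' values near 1 indicate the two classifiers succeed and fail on the same
#' samples, and -1 indicates perfectly complementary errors. Two statistically
#' independent classifiers have expected Q of 0. When the denominator is 0
#' (e.g. one classifier in the pair is never wrong) Q is returned as 0 with a
#' warning, which keeps redundancy pruning total.
#'
#' @param tab An `"agreement_table"`, or anything coercible to one via a list
#'   with components `n11`, `n10`, `n01`, `n00`.
#' @return Q in \[-1, 1\].
#' @examples
#' q_statistic(list(n11 = 40, n10 = 20, n01 = 10, n00 = 30))  # 5/7
#' @export
q_statistic <- function(tab) {
  tab <- as_agreement_table(tab)
  total <- tab$n11 + tab$n10 + tab$n01 + tab$n00
  if (total <= 0) stop("agreement table is empty", call. = FALSE)
  concord <- as.numeric(tab$n11) * as.numeric(tab$n00)
  discord <- as.numeric(tab$n01) * as.numeric(tab$n10)
  if (concord + discord == 0) {
    warning("Q-statistic undefined (zero denominator); returning 0",
            call. = FALSE)
    return(0)
  }
  (concord - discord) / (concord + discord)
}

as_agreement_table <- function(tab) {
  if (inherits(tab, "agreement_table")) return(tab)
  if (is.list(tab) && all(c("n11", "n10", "n01", "n00") %in% names(tab))) {
    cells <- lapply(tab[c("n11", "n10", "n01", "n00")], as.numeric)
    if (any(unlist(cells) < 0)) stop("negative cell count", call. = FALSE)
    return(structure(cells, class = "agreement_table"))
  }
  stop("cannot interpret input as an agreement table", call. = FALSE)
}

#' Pairwise Q matrix over a set of classifiers
#'
#' Builds the symmetric matrix of pairwise Q-statistics from hard-label
#' predictions of L classifiers on a common evaluation set. The diagonal is
#' set to 1 by convention and excluded from the ensemble average.
#'
#' @param y_true Observed 0/1 labels.
#' @param predictions A named list (or matrix with named columns, one per
#'   classifier) of 0/1 predicted label vectors on the same samples.
#' @return An object of class `"diversity_matrix"`: a list with `models`
#'   (names), `q` (symmetric L x L matrix), and `q_avg` (upper-triangle mean).
#' @export
q_matrix <- function(y_true, predictions) {
  if (is.matrix(predictions) || is.data.frame(predictions))
    predictions <- as.list(as.data.frame(predictions))
  if (length(predictions) < 2L)
    stop("need at least two classifiers", call. = FALSE)
  if (is.null(names(predictions)) || anyDuplicated(names(predictions)))
    stop("predictions must be uniquely named", call. = FALSE)
  l <- length(predictions)
  q <- diag(1, l)
  dimnames(q) <- list(names(predictions), names(predictions))
  for (i in seq_len(l - 1L)) {
    for (k in seq(i + 1L, l)) {
      qi <- suppressWarnings(
        q_statistic(agreement_table(y_true, predictions[[i]], predictions[[k]]))
      )
      q[i, k] <- q[k, i] <- qi
    }
  }
  structure(list(models = names(predictions), q = q, q_avg = q_average(q)),
            class = "diversity_matrix")
}

#' Ensemble-average Q
#'
#' Mean of the L(L-1)/2 distinct pairwise Q values, i.e. the strict upper
#' triangle of the pairwise matrix.
#'
#' @param q A `"diversity_matrix"`, a symmetric numeric matrix of pairwise Q
#'   values, or a numeric vector of the distinct pairwise values.
#' @return The average Q.
#' @examples
#' q_average(c(0.2, 0.4, 0.6))  # 0.4
#' @export
q_average <- function(q) {
  if (inherits(q, "diversity_matrix")) q <- q$q
  if (is.matrix(q)) {
    if (nrow(q) != ncol(q) || nrow(q) < 2L)
      stop("need a square matrix over at least two models", call. = FALSE)
    return(mean(q[upper.tri(q)]))
  }
  q <- as.numeric(q)
  if (length(q) < 1L) stop("need at least one pairwise value", call. = FALSE)
  mean(q)
}

#' @export
print.diversity_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise Q-statistics (", length(x$models), " models), Q_avg = ",
      round(x$q_avg, digits), "\n", sep = "")
  print(round(x$q, digits))
  invisible(x)
}

#' @export
as.data.frame.diversity_matrix <- function(x, ...) {
  as.data.frame(x$q)
}
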