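# Gradient-boosting feature filter with Shapley-value attributions.
# A GBDT is fitted to the label and each feature's global contribution is
# summarised as the mean absolute per-sample Shapley attribution on the raw
# margin (log-odds) scale; features below a cutoff are dropped.

#' Fit the attribution (feature-filter) model
#'
#' Fits a gradient-boosted tree ensemble to the binary label. Attributions
#' are computed on the model's raw margin (log-odds) output, on which the
#' baseline-plus-attributions decomposition is exactly additive.
#'
#' @param data Feature table with the binary label column.
#' @param label Name of the label column.
#' @param params GBDT hyperparameters; defaults are 100 trees of depth 3 at
#'   learning rate 0.1.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return An object of class `"attribution_model"` holding the fitted
#'   booster, the training feature names, and the baseline (expected margin).
#' @export
fit_attribution_model <- function(data, label = "Diabetes_binary",
                                  params = list(nrounds = 100L,
                                                max_depth = 3L, eta = 0.1),
                                  seed = 1L) {
  xy <- split_xy(data, label)
  if (length(unique(xy$y)) < 2L)
    stop("attribution model needs both classes present", call. = FALSE)
  if (min(table(xy$y)) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  params <- utils::modifyList(list(nrounds = 100L, max_depth = 3L, eta = 0.1),
                              params)
  nrounds <- params$nrounds
  params$nrounds <- NULL
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = utils::modifyList(list(objective = "binary:logistic",
                                    nthread = 1L), params),
    data = xgboost::xgb.DMatrix(xy$x, label = xy$y),
    nrounds = nrounds, verbose = 0)
  contrib <- predict(booster, xgboost::xgb.DMatrix(xy$x), predcontrib = TRUE)
  structure(list(booster = booster, features = colnames(xy$x), label = label,
                 baseline = contrib[1, ncol(contrib)], seed = seed),
            class = "attribution_model")
}

#' Per-sample Shapley attributions
#'
#' Tree-Shapley attributions of the model's raw margin output for every
#' sample: for each row, `baseline + rowSums(attributions)` equals the
#' model's margin prediction (local accuracy).
#'
#' @param model An `"attribution_model"`.
#' @param data Feature table containing the model's training features.
#' @return Numeric matrix (samples x features) with a `"baseline"` attribute.
#' @export
shap_values <- function(model, data) {
  stopifnot(inherits(model, "attribution_model"))
  x <- feature_matrix(data, model$features)
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(x),
                     predcontrib = TRUE)
  baseline <- contrib[1, ncol(contrib)]
  contrib <- contrib[, seq_along(model$features), drop = FALSE]
  colnames(contrib) <- model$features
  attr(contrib, "baseline") <- baseline
  contrib
}

#' Global feature contributions
#'
#' Summarises per-sample attributions into one non-negative global
#' contribution per feature: the mean absolute Shapley attribution over the
#' supplied table, ranked in descending order.
#'
#' @inheritParams shap_values
#' @return An object of class `"contribution_summary"`: a data frame with
#'   columns `feature`, `mean_abs_contribution` and `rank` (1 = largest).
#' @export
contribution_summary <- function(model, data) {
  sv <- shap_values(model, data)
  contrib <- colMeans(abs(sv))
  ord <- order(contrib, decreasing = TRUE)
  out <- data.frame(feature = names(contrib)[ord],
                    mean_abs_contribution = unname(contrib[ord]),
                    rank = seq_along(contrib),
                    stringsAsFactors = FALSE)
  class(out) <- c("contribution_summary", "data.frame")
  out
}

#' Filter features by global contribution
#'
#' Keeps features whose mean absolute contribution is at least the cutoff
#' (so the filter is idempotent and monotone in the cutoff). The label column
#' and the original column order are preserved. The 0.1 default mirrors the
#' cutoff under which low-signal care-access indicators are discarded in the
#' reference analysis.
#'
#' @param summary A `"contribution_summary"`.
#' @param data Feature table to restrict.
#' @param cutoff Non-negative contribution threshold (margin scale).
#' @param label Name of the label column, always retained.
#' @return `data` restricted to the surviving features plus the label.
#' @export
filter_features <- function(summary, data, cutoff = 0.1,
                            label = "Diabetes_binary") {
  stopifnot(inherits(summary, "contribution_summary"), cutoff >= 0)
  keep <- summary$feature[summary$mean_abs_contribution >= cutoff]
  if (length(keep) == 0L)
    stop(sprintf(
      "feature filter removed all features (cutoff = %g); lower the cutoff",
      cutoff), call. = FALSE)
  cols <- names(data)[names(data) %in% c(keep, label)]
  data[cols]
}

#' @export
print.contribution_summary <- function(x, digits = 4, n = 10, ...) {
  cat("Global feature contributions (mean |Shapley attribution|, margin scale)\n")
  print.data.frame(utils::head(x, n), digits = digits, row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more features\n")
  invisible(x)
}
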