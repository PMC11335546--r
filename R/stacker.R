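# Adaptive stacking engine. Base classifiers are chosen from a zoo of
# candidates by (1) cross-validated F1 against a threshold (by default the
# mean F1 of the zoo, so only better-than-average models survive) and
# (2) greedy Q-statistic pruning of redundant pairs, following the
# error-ambiguity decomposition: ensemble error = mean member error minus
# member diversity, so members should be accurate AND diverse. Surviving
# bases feed a two-layer stack: out-of-fold probabilities form the
# meta-feature matrix (no leakage), fold-model predictions on the test side
# are averaged, and the meta-learner is chosen by traversal of candidate
# families on the meta-features.

#' Configuration for adaptive base-classifier selection and stacking
#'
#' @param f1_threshold `"mean"` to use the average cross-validated F1 of the
#'   zoo as the selection threshold, or an explicit numeric threshold
#'   (`-Inf` disables the screen). Survival is strict: F1 > threshold.
#' @param q_cutoff Redundancy cutoff in \[0, 1\]: while any surviving pair
#'   has |Q| above it, the pair member with lower cross-validated accuracy is
#'   dropped. 1 disables pruning; the 0.9 default flags only near-duplicate
#'   models.
#' @param folds Number of stratified cross-validation folds (default 5).
#' @param train_fraction Fraction of rows in the training split of the
#'   stratified train/test split (default 0.8, an 8:2 split).
#' @param meta_candidates `"selected"` traverses the surviving base families
#'   as meta-learner candidates, `"all"` traverses the whole zoo,
#'   `"lr"` fixes logistic regression.
#' @param meta_feature_type `"proba"` (default) stacks positive-class
#'   probabilities; `"label"` stacks hard 0/1 predictions.
#' @param min_per_class Minimum samples per class required by [adaptive_stacking()].
#' @param seed Integer master seed; all splits, folds and model seeds derive
#'   from it.
#' @return An object of class `"selection_config"`.
#' @export
selection_config <- function(f1_threshold = "mean", q_cutoff = 0.9,
                             folds = 5L, train_fraction = 0.8,
                             meta_candidates = c("selected", "all", "lr"),
                             meta_feature_type = c("proba", "label"),
                             min_per_class = 50L, seed = 1L) {
  if (!(identical(f1_threshold, "mean") || is.numeric(f1_threshold)))
    stop("f1_threshold must be \"mean\" or numeric", call. = FALSE)
  stopifnot(q_cutoff >= 0, q_cutoff <= 1, folds >= 2L,
            train_fraction > 0, train_fraction < 1)
  structure(list(f1_threshold = f1_threshold, q_cutoff = q_cutoff,
                 folds = as.integer(folds), train_fraction = train_fraction,
                 meta_candidates = match.arg(meta_candidates),
                 meta_feature_type = match.arg(meta_feature_type),
                 min_per_class = as.integer(min_per_class),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Configuration reducing the engine to a traditional stacking ensemble
#'
#' Disables the F1 screen and the diversity pruning and fixes logistic
#' regression as the meta-learner, the conventional stacked-generalization
#' baseline.
#'
#' @param ... Passed on to [selection_config()].
#' @export
traditional_stacking_config <- function(...) {
  selection_config(f1_threshold = -Inf, q_cutoff = 1,
                   meta_candidates = "lr", ...)
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds so that every fold has a
#' near-equal share of each class.
#'
#' @param y 0/1 label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- check_binary(y, "y")
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds", call. = FALSE)
  if (min(table(factor(y, c(0, 1)))) < k)
    stop("stratification error: fewer samples than folds in a class",
         call. = FALSE)
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Stratified train/test split; returns logical vector (TRUE = train).
stratified_split <- function(y, train_fraction, seed) {
  set.seed(seed)
  in_train <- logical(length(y))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    n_tr <- round(length(idx) * train_fraction)
    in_train[idx[seq_len(n_tr)]] <- TRUE
  }
  in_train
}

#' Apply the F1 threshold screen to a set of model F1 values
#'
#' Pure selection step, usable on externally supplied cross-validated F1
#' values: the threshold is the mean F1 (or an explicit value), and models
#' survive only with F1 strictly above it.
#'
#' @param f1 Named numeric vector of per-model F1 values.
#' @param threshold `"mean"` or an explicit numeric threshold.
#' @return List with `lambda` (the threshold used), `survivors` and
#'   `excluded` (character vectors of model names).
#' @examples
#' apply_f1_threshold(c(a = 0.7, b = 0.8))  # lambda 0.75, survivor "b"
#' @export
apply_f1_threshold <- function(f1, threshold = "mean") {
  if (is.null(names(f1)) || anyDuplicated(names(f1)))
    stop("f1 must be uniquely named", call. = FALSE)
  lambda <- if (identical(threshold, "mean")) mean(f1) else as.numeric(threshold)
  list(lambda = lambda,
       survivors = names(f1)[f1 > lambda],
       excluded = names(f1)[f1 <= lambda])
}

#' Greedy Q-statistic redundancy pruning
#'
#' While any pair of remaining models has |Q| above the cutoff, the pair
#' with the largest |Q| is located and its member with the lower accuracy is
#' eliminated; Q comparisons then continue on the reduced set. Pure in its
#' inputs, so a logged selection can be replayed.
#'
#' @param q Symmetric matrix of pairwise Q values with model-name dimnames
#'   (or a `"diversity_matrix"`).
#' @param accuracy Named accuracy vector used to decide which pair member to
#'   drop (ties drop the later model in matrix order).
#' @param q_cutoff Redundancy cutoff in \[0, 1\].
#' @return List with `keep` (character vector) and `eliminations` (data frame
#'   with columns `model`, `reason`).
#' @export
prune_redundant <- function(q, accuracy, q_cutoff = 0.9) {
  if (inherits(q, "diversity_matrix")) q <- q$q
  stopifnot(is.matrix(q), nrow(q) == ncol(q))
  models <- rownames(q)
  if (is.null(models) || !all(models %in% names(accuracy)))
    stop("q must have dimnames covered by names(accuracy)", call. = FALSE)
  elim <- data.frame(model = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  keep <- models
  repeat {
    if (length(keep) < 2L) break
    sub <- abs(q[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) <= q_cutoff) break
    pair <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- keep[pair[["row"]]]
    b <- keep[pair[["col"]]]
    drop <- if (accuracy[[a]] < accuracy[[b]]) a
            else if (accuracy[[b]] < accuracy[[a]]) b
            else keep[max(pair)]
    kept <- setdiff(c(a, b), drop)
    elim <- rbind(elim, data.frame(model = drop,
                                   reason = paste0("redundant-with:", kept),
                                   stringsAsFactors = FALSE))
    keep <- setdiff(keep, drop)
  }
  list(keep = keep, eliminations = elim)
}

# Out-of-fold cross-validation of one spec. Returns OOF probabilities and,
# optionally, per-fold models and their averaged predictions on `test`.
cv_oof <- function(spec, data, label, fold, test = NULL, keep_models = FALSE) {
  k <- max(fold)
  n <- nrow(data)
  oof <- numeric(n)
  models <- if (keep_models) vector("list", k) else NULL
  test_pred <- if (!is.null(test)) matrix(NA_real_, nrow(test), k) else NULL
  for (f in seq_len(k)) {
    hold <- fold == f
    m <- train_model(spec, data[!hold, , drop = FALSE], label)
    oof[hold] <- predict_proba(m, data[hold, , drop = FALSE])
    if (!is.null(test)) test_pred[, f] <- predict_proba(m, test)
    if (keep_models) models[[f]] <- m
  }
  list(oof = oof, models = models,
       test = if (!is.null(test)) rowMeans(test_pred) else NULL)
}

#' Adaptive selection of base classifiers
#'
#' Runs the selection stage on a training table: each zoo member's F1 and
#' accuracy are estimated by pooled out-of-fold predictions on one shared
#' stratified fold assignment (shared folds make the correctness patterns of
#' different models comparable sample by sample); the F1 screen and the
#' greedy Q-statistic pruning are then applied. Every elimination is logged
#' with its reason.
#'
#' @param zoo Named list of `"model_spec"` objects (>= 2).
#' @param data Training feature table including the label column.
#' @param label Name of the label column.
#' @param config A `"selection_config"`.
#' @return An object of class `"selection_trace"` with components `f1`,
#'   `cv_accuracy` (named vectors), `lambda`, `threshold_mode`, `survivors`,
#'   `diversity` (a `"diversity_matrix"` on the survivors, or NULL),
#'   `eliminations` (data frame `model`, `reason`), `selected`, `folds`
#'   (fold assignment) and `oof` (matrix of out-of-fold probabilities, one
#'   column per zoo member).
#' @export
select_base_classifiers <- function(zoo, data, label = "Diabetes_binary",
                                    config = selection_config()) {
  stopifnot(inherits(config, "selection_config"), length(zoo) >= 2L)
  if (is.null(names(zoo)))
    names(zoo) <- vapply(zoo, function(s) s$name, character(1))
  if (anyDuplicated(names(zoo)))
    stop("zoo model names must be unique", call. = FALSE)
  y <- check_binary(data[[label]], label)
  fold <- stratified_folds(y, config$folds, derive_seed(config$seed, 11L))
  oof <- matrix(NA_real_, nrow(data), length(zoo),
                dimnames = list(NULL, names(zoo)))
  for (nm in names(zoo))
    oof[, nm] <- cv_oof(zoo[[nm]], data, label, fold)$oof
  hard <- (oof >= 0.5) * 1L
  f1 <- apply(hard, 2, function(p)
    suppressWarnings(f1_score(confusion_counts(y, p))))
  acc <- apply(hard, 2, function(p) accuracy(confusion_counts(y, p)))
  thr <- apply_f1_threshold(f1, config$f1_threshold)
  elim <- data.frame(model = thr$excluded,
                     reason = rep("below-threshold", length(thr$excluded)),
                     stringsAsFactors = FALSE)
  if (length(thr$survivors) == 0L)
    stop("selection failure: no model exceeds the F1 threshold",
         call. = FALSE)
  diversity <- NULL
  selected <- thr$survivors
  if (length(selected) >= 2L) {
    diversity <- q_matrix(y, as.data.frame(hard[, selected, drop = FALSE]))
    pruned <- prune_redundant(diversity$q, acc, config$q_cutoff)
    selected <- pruned$keep
    elim <- rbind(elim, pruned$eliminations)
  }
  if (length(selected) == 1L)
    warning("single base classifier selected; stacking degenerates to that ",
            "model plus a meta-learner", call. = FALSE)
  structure(list(f1 = f1, cv_accuracy = acc, lambda = thr$lambda,
                 threshold_mode = config$f1_threshold,
                 survivors = thr$survivors, diversity = diversity,
                 eliminations = elim, selected = selected, folds = fold,
                 oof = oof, config = config),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, digits = 4, ...) {
  cat("Adaptive base-classifier selection\n")
  cat("  CV F1:", paste(sprintf("%s=%.*f", names(x$f1), digits, x$f1),
                        collapse = " "), "\n")
  cat("  threshold lambda =", round(x$lambda, 5), "\n")
  cat("  survivors:", paste(x$survivors, collapse = ", "), "\n")
  if (nrow(x$eliminations))
    cat("  eliminated:",
        paste(sprintf("%s (%s)", x$eliminations$model, x$eliminations$reason),
              collapse = "; "), "\n")
  cat("  final base set:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Build the stacked (convergence-layer) feature matrices
#'
#' For each base classifier, `k` stratified fold-models are trained on the
#' training split: each fold-model predicts its held-out fold, and the k
#' held-out prediction blocks are stacked vertically into one out-of-fold
#' column of length n_train, so no training sample is ever predicted by a
#' model that saw it. Each fold-model also predicts the full test table and
#' the k prediction vectors are averaged element-wise into the test column.
#'
#' @param specs Named list of `"model_spec"` objects for the base
#'   classifiers.
#' @param train,test Training and test feature tables with the label column
#'   (`test` label optional at prediction time but required here for
#'   evaluation flows; it is not used to build features).
#' @param label Name of the label column.
#' @param config A `"selection_config"` (folds and seed are used).
#' @return An object of class `"stacked_features"` with `train_meta` and
#'   `test_meta` matrices (columns in base order), `bases`, `folds` (the
#'   fold assignment record) and `fold_models` (k retained models per base,
#'   reused at prediction time).
#' @export
build_stacked_features <- function(specs, train, test,
                                   label = "Diabetes_binary",
                                   config = selection_config()) {
  stopifnot(length(specs) >= 1L)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$name, character(1))
  y <- check_binary(train[[label]], label)
  fold <- stratified_folds(y, config$folds, derive_seed(config$seed, 23L))
  test_x <- test[setdiff(names(test), label)]
  b <- length(specs)
  train_meta <- matrix(NA_real_, nrow(train), b,
                       dimnames = list(NULL, names(specs)))
  test_meta <- matrix(NA_real_, nrow(test), b,
                      dimnames = list(NULL, names(specs)))
  fold_models <- vector("list", b)
  names(fold_models) <- names(specs)
  for (nm in names(specs)) {
    res <- cv_oof(specs[[nm]], train, label, fold, test = test_x,
                  keep_models = TRUE)
    train_meta[, nm] <- res$oof
    test_meta[, nm] <- res$test
    fold_models[[nm]] <- res$models
  }
  if (config$meta_feature_type == "label") {
    train_meta <- (train_meta >= 0.5) * 1
    test_meta <- (test_meta >= 0.5) * 1
  }
  structure(list(train_meta = train_meta, test_meta = test_meta,
                 bases = names(specs), folds = fold,
                 fold_models = fold_models,
                 meta_feature_type = config$meta_feature_type),
            class = "stacked_features")
}

#' Choose the meta-learner by traversal
#'
#' Evaluates every candidate family by k-fold cross-validated F1 on the
#' stacked training features, then refits the best candidate (ties broken by
#' higher cross-validated accuracy, then candidate order) on the full
#' meta-feature matrix.
#'
#' @param candidates Named list of `"model_spec"` objects.
#' @param stacked A `"stacked_features"` object.
#' @param y_train 0/1 labels of the training split.
#' @param config A `"selection_config"`.
#' @return List with `model` (the refitted `"trained_model"`) and `scores`
#'   (data frame of per-candidate CV F1 and accuracy).
#' @export
select_meta_learner <- function(candidates, stacked, y_train,
                                config = selection_config()) {
  stopifnot(inherits(stacked, "stacked_features"), length(candidates) >= 1L)
  if (is.null(names(candidates)))
    names(candidates) <- vapply(candidates, function(s) s$name, character(1))
  y <- check_binary(y_train, "y_train")
  meta <- as.data.frame(stacked$train_meta)
  meta$.meta_label <- y
  fold <- stratified_folds(y, config$folds, derive_seed(config$seed, 31L))
  scores <- data.frame(candidate = names(candidates), f1 = NA_real_,
                       accuracy = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    oof <- tryCatch(
      cv_oof(candidates[[i]], meta, ".meta_label", fold)$oof,
      error = function(e) {
        warning(sprintf("meta-candidate '%s' failed: %s",
                        names(candidates)[i], conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(oof)) next
    hard <- as.integer(oof >= 0.5)
    scores$f1[i] <- suppressWarnings(f1_score(confusion_counts(y, hard)))
    scores$accuracy[i] <- accuracy(confusion_counts(y, hard))
  }
  if (all(is.na(scores$f1)))
    stop("meta-selection error: all candidates failed to train",
         call. = FALSE)
  ord <- order(-scores$f1, -scores$accuracy, seq_len(nrow(scores)),
               na.last = TRUE)
  best <- scores$candidate[ord[1]]
  model <- train_model(candidates[[best]], meta, ".meta_label")
  list(model = model, scores = scores, best = best)
}

#' Fit an adaptive stacking ensemble
#'
#' End-to-end constructor: a seeded stratified 8:2 train/test split, adaptive
#' base-classifier selection (F1 threshold + Q-statistic pruning) on the
#' training split, out-of-fold construction of the stacked feature matrices,
#' meta-learner traversal, and evaluation of the fitted ensemble on the
#' held-out test split. Fully deterministic given the configuration seed.
#'
#' @param data Feature table with the binary label column; needs at least
#'   `config$min_per_class` samples in each class.
#' @param label Name of the label column.
#' @param zoo Named list of candidate `"model_spec"` objects; defaults to the
#'   ten-family zoo seeded from the configuration seed.
#' @param config A `"selection_config"`.
#' @return An object of class `"adaptive_stacking"` with the selection
#'   `trace`, the retained fold models, the chosen meta-learner, the
#'   held-out `test_metrics` (a `"metrics_report"`) and the split record.
#' @export
adaptive_stacking <- function(data, label = "Diabetes_binary",
                              zoo = default_zoo(config$seed),
                              config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  y_all <- check_binary(data[[label]], label)
  if (min(table(factor(y_all, c(0, 1)))) < config$min_per_class)
    stop(sprintf("need at least %d samples per class", config$min_per_class),
         call. = FALSE)
  set.seed(derive_seed(config$seed, 7L))
  perm <- sample(nrow(data))
  data <- data[perm, , drop = FALSE]
  rownames(data) <- NULL
  y <- y_all[perm]
  in_train <- stratified_split(y, config$train_fraction,
                               derive_seed(config$seed, 13L))
  train <- data[in_train, , drop = FALSE]
  test <- data[!in_train, , drop = FALSE]
  trace <- with_stage("base-classifier selection",
    select_base_classifiers(zoo, train, label, config))
  stacked <- with_stage("stacked-feature construction",
    build_stacked_features(zoo[trace$selected], train, test, label, config))
  candidates <- switch(config$meta_candidates,
    selected = zoo[trace$selected],
    all = zoo,
    lr = zoo[intersect("lr", names(zoo))] %missing% list(lr = model_spec(
      "lr", seed = derive_seed(config$seed, 41L))))
  meta <- with_stage("meta-learner selection",
    select_meta_learner(candidates, stacked, train[[label]], config))
  test_proba <- as.numeric(predict_proba(
    meta$model, as.data.frame(stacked$test_meta)))
  test_metrics <- metrics_report(test[[label]],
                                 as.integer(test_proba >= 0.5),
                                 test_proba, model = "Adaptive Stacking")
  structure(list(trace = trace, stacked = stacked, meta = meta,
                 config = config, label = label,
                 features = setdiff(names(data), label),
                 test_metrics = test_metrics,
                 split = list(perm = perm, in_train = in_train)),
            class = "adaptive_stacking")
}

`%missing%` <- function(a, b) if (length(a)) a else b

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' @export
print.adaptive_stacking <- function(x, ...) {
  cat("Adaptive stacking ensemble\n")
  cat("  bases:", paste(x$trace$selected, collapse = ", "), "\n")
  cat("  meta-learner:", x$meta$best, "\n")
  cat("  held-out test metrics:\n")
  print(x$test_metrics)
  invisible(x)
}

#' Predict from an adaptive stacking ensemble
#'
#' Reconstructs the meta-feature row for each new sample exactly as at fit
#' time: each base's k retained fold-models predict the sample and their
#' probabilities are averaged; the meta-learner then maps the meta-features
#' to a probability.
#'
#' @param object An `"adaptive_stacking"` ensemble.
#' @param newdata Feature table with the training features.
#' @param type `"class"` for 0/1 labels, `"prob"` for positive-class
#'   probabilities.
#' @param threshold Probability cut for `type = "class"`.
#' @param ... Unused.
#' @return Numeric vector of labels or probabilities.
#' @export
predict.adaptive_stacking <- function(object, newdata,
                                      type = c("class", "prob"),
                                      threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- newdata[intersect(names(newdata), object$features)]
  if (!setequal(names(x), object$features))
    stop("newdata is missing training features", call. = FALSE)
  meta <- vapply(object$stacked$fold_models, function(models) {
    per_fold <- matrix(unlist(lapply(models, predict_proba, data = x)),
                       nrow = nrow(x))
    rowMeans(per_fold)
  }, numeric(nrow(x)))
  meta <- matrix(meta, nrow = nrow(x),
                 dimnames = list(NULL, object$stacked$bases))
  if (object$stacked$meta_feature_type == "label") meta <- (meta >= 0.5) * 1
  proba <- as.numeric(predict_proba(object$meta$model, as.data.frame(meta)))
  if (type == "prob") proba else as.integer(proba >= threshold)
}
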