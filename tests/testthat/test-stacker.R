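test_that("the F1 threshold screen reproduces the reference worked selection", {
  thr <- apply_f1_threshold(reference_f1, threshold = "mean")
  expect_equal(thr$lambda, mean(reference_f1))
  expect_equal(round(thr$lambda, 5), 0.75091)
  expect_setequal(thr$excluded, c("knn", "rf", "lr", "dt"))
  expect_setequal(thr$survivors,
                  c("svm", "gbdt", "xgboost", "lightgbm", "catboost", "mlp"))
})

test_that("greedy Q pruning keeps the most accurate member of a redundant cluster", {
  models <- c("gbdt", "lightgbm", "catboost", "svm")
  q <- diag(1, 4)
  dimnames(q) <- list(models, models)
  q["gbdt", "lightgbm"] <- q["lightgbm", "gbdt"] <- 0.97
  q["gbdt", "catboost"] <- q["catboost", "gbdt"] <- 0.95
  q["lightgbm", "catboost"] <- q["catboost", "lightgbm"] <- 0.96
  q["svm", "gbdt"] <- q["gbdt", "svm"] <- 0.3
  acc <- c(gbdt = 0.7536, lightgbm = 0.7547, catboost = 0.7557, svm = 0.7449)
  pruned <- prune_redundant(q, acc, q_cutoff = 0.9)
  expect_setequal(pruned$keep, c("catboost", "svm"))
  expect_setequal(pruned$eliminations$model, c("gbdt", "lightgbm"))
  expect_true(all(grepl("^redundant-with:", pruned$eliminations$reason)))

  # cutoff 1 disables pruning entirely
  none <- prune_redundant(q, acc, q_cutoff = 1)
  expect_setequal(none$keep, models)
  expect_equal(nrow(none$eliminations), 0L)

  # raising the cutoff never shrinks the kept set (monotone pruning)
  kept <- lapply(c(0.2, 0.5, 0.9, 1), function(tau)
    prune_redundant(q, acc, q_cutoff = tau)$keep)
  for (i in seq_len(length(kept) - 1L))
    expect_true(all(kept[[i]] %in% kept[[i + 1L]]))
})

test_that("raising the F1 threshold never grows the survivor set", {
  lambdas <- c(-Inf, 0.72, 0.75, 0.76, 0.77)
  surv <- lapply(lambdas, function(l)
    apply_f1_threshold(reference_f1, threshold = l)$survivors)
  for (i in seq_len(length(surv) - 1L))
    expect_true(all(surv[[i + 1L]] %in% surv[[i]]))
})

test_that("a permissive configuration keeps every zoo member", {
  cfg <- selection_config(f1_threshold = -Inf, q_cutoff = 1, folds = 4L,
                          min_per_class = 20L, seed = 3L)
  tab <- simulate_brfss(small_config(n = 240, seed = 5))
  trace <- select_base_classifiers(fast_zoo(3), tab, config = cfg)
  expect_setequal(trace$selected, names(fast_zoo(3)))
  expect_equal(nrow(trace$eliminations), 0L)
  expect_equal(trace$lambda, -Inf)
})

test_that("duplicated specs are flagged as perfectly dependent and one is pruned", {
  cfg <- selection_config(f1_threshold = -Inf, q_cutoff = 0.99, folds = 4L,
                          min_per_class = 20L, seed = 7L)
  zoo <- fast_zoo(2, families = c("lr", "dt"))
  zoo$lr_copy <- zoo$lr
  zoo$lr_copy$name <- "lr_copy"
  tab <- simulate_brfss(small_config(n = 240, seed = 9))
  trace <- select_base_classifiers(zoo, tab, config = cfg)
  expect_equal(trace$diversity$q["lr", "lr_copy"], 1)
  expect_true(xor("lr" %in% trace$selected, "lr_copy" %in% trace$selected))
  elim <- trace$eliminations
  expect_true(any(elim$model %in% c("lr", "lr_copy") &
                    grepl("^redundant-with:lr", elim$reason)))
})

test_that("selection replay from the logged F1s and Q matrix reproduces the outcome", {
  cfg <- selection_config(folds = 4L, q_cutoff = 0.95, min_per_class = 20L,
                          seed = 11L)
  tab <- simulate_brfss(small_config(n = 260, seed = 2))
  trace <- select_base_classifiers(fast_zoo(5), tab, config = cfg)
  thr <- apply_f1_threshold(trace$f1, cfg$f1_threshold)
  expect_equal(thr$lambda, trace$lambda)
  expect_setequal(thr$survivors, trace$survivors)
  replay <- if (length(thr$survivors) >= 2L)
    prune_redundant(trace$diversity$q, trace$cv_accuracy, cfg$q_cutoff)$keep
  else thr$survivors
  expect_setequal(replay, trace$selected)
})

test_that("stacked feature matrices have the contract shape and base order", {
  tab <- simulate_brfss(small_config(n = 125, seed = 4))
  train <- tab[1:100, ]
  test <- tab[101:125, ]
  specs <- fast_zoo(4, families = c("lr", "dt", "knn", "gbdt"))
  cfg <- selection_config(folds = 5L, min_per_class = 10L, seed = 2L)
  sf <- build_stacked_features(specs, train, test, config = cfg)
  expect_equal(dim(sf$train_meta), c(100L, 4L))
  expect_equal(dim(sf$test_meta), c(25L, 4L))
  expect_identical(colnames(sf$train_meta), names(specs))
  expect_identical(sf$bases, names(specs))
  expect_true(all(sf$train_meta >= 0 & sf$train_meta <= 1))
  expect_equal(sort(unique(sf$folds)), 1:5)
  expect_length(sf$fold_models$lr, 5L)
})

test_that("a constant-output base propagates as a constant meta column", {
  # a root-only decision tree on an exactly balanced table predicts the
  # class-1 training share, which stratified folds keep at exactly 1/2
  set.seed(8)
  tab <- data.frame(f1 = rnorm(120), f2 = rnorm(120),
                    y = rep(c(0L, 1L), 60))
  specs <- list(stump = model_spec("dt", name = "stump",
                                   params = list(cp = 1, minsplit = 200L),
                                   seed = 1))
  cfg <- selection_config(folds = 4L, min_per_class = 10L, seed = 5L)
  sf <- build_stacked_features(specs, tab[1:100, ], tab[101:120, ],
                               label = "y", config = cfg)
  expect_equal(as.numeric(sf$train_meta), rep(0.5, 100))
  expect_equal(as.numeric(sf$test_meta), rep(0.5, 20))
})

test_that("out-of-fold construction does not leak training labels", {
  # memorizing base (1-nearest-neighbour) on pure-noise labels:
  # resubstitution predictions are perfect, legitimate OOF ones are not
  set.seed(10)
  tab <- data.frame(f1 = rnorm(150), f2 = rnorm(150),
                    y = rbinom(150, 1, 0.5))
  spec <- model_spec("knn", params = list(k = 1L), seed = 3)
  resub <- predict_label(train_model(spec, tab, "y"), tab)
  expect_equal(mean(resub == tab$y), 1)  # memorization confirmed
  cfg <- selection_config(folds = 5L, min_per_class = 10L, seed = 6L)
  sf <- build_stacked_features(list(knn = spec), tab, tab[1:10, ],
                               label = "y", config = cfg)
  oof_acc <- mean(as.integer(sf$train_meta[, 1] >= 0.5) == tab$y)
  expect_lt(oof_acc, 0.75)
  # fold bookkeeping: every sample has a fold, folds are near-balanced
  expect_length(sf$folds, 150L)
  expect_true(max(table(sf$folds)) - min(table(sf$folds)) <= 2)
})

test_that("meta-learner traversal picks the candidate that decodes an oracle column", {
  set.seed(13)
  y <- rbinom(120, 1, 0.5)
  sf <- structure(list(
    train_meta = cbind(oracle = y, noise = runif(120)),
    test_meta = NULL, bases = c("oracle", "noise"), folds = NULL,
    fold_models = NULL, meta_feature_type = "proba"),
    class = "stacked_features")
  cands <- list(lr = model_spec("lr", seed = 2),
                dt = model_spec("dt", seed = 2))
  cfg <- selection_config(folds = 4L, min_per_class = 10L, seed = 8L)
  res <- select_meta_learner(cands, sf, y, cfg)
  expect_gte(max(res$scores$f1, na.rm = TRUE), 0.99)
  expect_equal(res$scores$candidate[which.max(res$scores$f1)], res$best)
  # single candidate: trivially selected
  one <- select_meta_learner(cands["lr"], sf, y, cfg)
  expect_identical(one$best, "lr")
})

test_that("the fitted ensemble separates strong-signal data and is self-consistent", {
  blob <- make_blob(n = 300, margin = 3, seed = 21, label = "y")
  cfg <- selection_config(f1_threshold = 0.5, q_cutoff = 1, folds = 4L,
                          min_per_class = 20L, seed = 17L)
  zoo <- fast_zoo(17, families = c("lr", "dt", "knn", "gbdt"))
  fit <- adaptive_stacking(blob, label = "y", zoo = zoo, config = cfg)
  expect_gte(fit$test_metrics$f1, 0.9)

  # predicting the fit-time test split reproduces the fit-time report
  shuffled <- blob[fit$split$perm, , drop = FALSE]
  test_rows <- shuffled[!fit$split$in_train, , drop = FALSE]
  proba <- predict(fit, test_rows, type = "prob")
  rep2 <- metrics_report(test_rows$y, as.integer(proba >= 0.5), proba)
  expect_equal(rep2$f1, fit$test_metrics$f1)
  expect_equal(rep2$auc, fit$test_metrics$auc)

  # well-formed single-row prediction, probabilities in range
  p1 <- predict(fit, blob[5, , drop = FALSE], type = "prob")
  expect_length(p1, 1L)
  expect_true(p1 >= 0 && p1 <= 1)
  expect_true(predict(fit, blob[5, , drop = FALSE]) %in% c(0L, 1L))
})

test_that("fitting is deterministic under a fixed seed", {
  tab <- simulate_brfss(small_config(n = 280, seed = 30))
  cfg <- selection_config(f1_threshold = 0.5, q_cutoff = 1, folds = 4L,
                          min_per_class = 20L, seed = 23L)
  zoo <- fast_zoo(23, families = c("lr", "dt", "gbdt"))
  f1 <- adaptive_stacking(tab, zoo = zoo, config = cfg)
  f2 <- adaptive_stacking(tab, zoo = zoo, config = cfg)
  expect_equal(f1$trace$f1, f2$trace$f1)
  expect_identical(f1$trace$selected, f2$trace$selected)
  expect_identical(f1$meta$best, f2$meta$best)
  probe <- simulate_brfss(small_config(n = 50, seed = 31))
  expect_equal(predict(f1, probe, type = "prob"),
               predict(f2, probe, type = "prob"))
})

test_that("a permissive fixed-LR configuration reduces to traditional stacking", {
  tab <- simulate_brfss(small_config(n = 260, seed = 40))
  cfg <- traditional_stacking_config(folds = 4L, min_per_class = 20L,
                                     seed = 29L)
  zoo <- fast_zoo(29, families = c("lr", "dt", "knn"))
  fit <- adaptive_stacking(tab, zoo = zoo, config = cfg)
  expect_setequal(fit$trace$selected, names(zoo))   # nothing screened out
  expect_equal(nrow(fit$trace$eliminations), 0L)
  expect_identical(fit$meta$model$spec$family, "lr")  # fixed meta-learner
})

test_that("degenerate inputs surface stage-tagged errors", {
  tab <- simulate_brfss(small_config(n = 80, seed = 50))
  cfg <- selection_config(min_per_class = 200L, seed = 1L)
  expect_error(adaptive_stacking(tab, zoo = fast_zoo(1), config = cfg),
               "samples per class")
  cfg2 <- selection_config(f1_threshold = 2, folds = 3L, min_per_class = 10L,
                           seed = 1L)
  expect_error(
    adaptive_stacking(tab, zoo = fast_zoo(1, c("lr", "dt")), config = cfg2),
    "\\[base-classifier selection\\].*no model exceeds")
})
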