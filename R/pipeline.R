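# End-to-end orchestration: normalization -> attribution feature filter ->
# adaptive stacking -> evaluation, with a run directory of artifacts
# (metrics CSV, ROC points, selection trace, contribution summary, config
# snapshot, log). Normalization and feature filtering are fitted on the
# training rows only and frozen for held-out rows.

#' Min-max normalization fitted on a row subset
#'
#' Rescales every feature column to \[0, 1\] using ranges estimated on
#' `fit_rows` only, so held-out rows never influence the transformation.
#' Constant features map to 0 with a warning. The label column is untouched.
#'
#' @param data Feature table.
#' @param fit_rows Row indices (or logical vector) on which ranges are
#'   estimated; defaults to all rows.
#' @param label Name of the label column.
#' @return The transformed table, with the fitted ranges in attribute
#'   `"normalization"`.
#' @export
normalize_minmax <- function(data, fit_rows = seq_len(nrow(data)),
                             label = "Diabetes_binary") {
  features <- setdiff(names(data), label)
  if (length(features) == 0L || nrow(data[fit_rows, , drop = FALSE]) == 0L)
    stop("fit_rows must select at least one row", call. = FALSE)
  ranges <- lapply(features, function(f) {
    v <- data[fit_rows, f]
    c(min = min(v), max = max(v))
  })
  names(ranges) <- features
  for (f in features) {
    r <- ranges[[f]]
    if (r["max"] == r["min"]) {
      warning(sprintf("feature '%s' is constant on the fitting rows; mapped to 0",
                      f), call. = FALSE)
      data[[f]] <- rep(0, nrow(data))
    } else {
      data[[f]] <- (data[[f]] - r["min"]) / (r["max"] - r["min"])
    }
  }
  attr(data, "normalization") <- ranges
  data
}

#' Run the full prediction pipeline
#'
#' Loads a CSV (or simulates from a generator configuration), optionally
#' min-max normalizes, filters features by Shapley contribution, fits the
#' adaptive stacking ensemble, and writes all artifacts to the output
#' directory: `metrics.csv` (comparison-table style), `roc_points.csv`,
#' `selection_trace.json`, `contributions.csv`, `config.yaml`,
#' `ensemble.rds` and `run.log`. Normalization ranges and the surviving
#' feature list are estimated on the training split of the 8:2 split only
#' and frozen for the test split.
#'
#' @param input Path to a CSV feature table, or a `"brfss_config"` to
#'   simulate one.
#' @param out_dir Output directory (created if needed).
#' @param label Name of the binary label column.
#' @param normalize Apply min-max normalization (default TRUE).
#' @param cutoff Attribution filter cutoff; 0 keeps every feature.
#' @param config A `"selection_config"`.
#' @param zoo Candidate model specs; default ten-family zoo.
#' @param compare Also evaluate every single zoo member and a traditional
#'   stacking baseline on the same split, adding one metrics row per model.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the fitted `ensemble`, the `metrics` data
#'   frame, the `contributions` summary and `out_dir`.
#' @export
run_pipeline <- function(input, out_dir, label = "Diabetes_binary",
                         normalize = TRUE, cutoff = 0.1,
                         config = selection_config(),
                         zoo = default_zoo(config$seed),
                         compare = FALSE, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (verbose) message(msg)
  }
  stage <- "input"
  on_fail <- function(e) {
    log_line("ERROR at stage [", stage, "]: ", conditionMessage(e))
    stop(sprintf("pipeline failed at stage [%s]: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    data <- if (inherits(input, "brfss_config")) {
      log_line("simulating ", input$n_samples, " rows from generator config")
      simulate_brfss(input)
    } else {
      log_line("reading ", input)
      utils::read.csv(input)
    }
    if (!label %in% names(data))
      stop(sprintf("label column '%s' not found", label))

    # the split must be decided before any fitted preprocessing
    y <- check_binary(data[[label]], label)
    set.seed(derive_seed(config$seed, 7L))
    perm <- sample(nrow(data))
    in_train_perm <- stratified_split(y[perm], config$train_fraction,
                                      derive_seed(config$seed, 13L))
    train_rows <- perm[in_train_perm]

    stage <- "normalization"
    if (normalize) {
      log_line("min-max normalization (ranges fitted on ",
               length(train_rows), " training rows)")
      data <- normalize_minmax(data, train_rows, label)
    }

    stage <- "feature-filter"
    att <- fit_attribution_model(data[train_rows, , drop = FALSE],
                                 label = label,
                                 seed = derive_seed(config$seed, 3L))
    contributions <- contribution_summary(att,
                                          data[train_rows, , drop = FALSE])
    data <- filter_features(contributions, data, cutoff, label)
    log_line("feature filter at cutoff ", cutoff, " retains ",
             ncol(data) - 1L, " of ", nrow(contributions), " features")

    stage <- "adaptive-stacking"
    ensemble <- adaptive_stacking(data, label, zoo, config)
    log_line("base set: ", paste(ensemble$trace$selected, collapse = ", "),
             "; meta-learner: ", ensemble$meta$best)

    stage <- "evaluation"
    metrics <- as.data.frame(ensemble$test_metrics)
    if (compare) {
      log_line("compare mode: evaluating ", length(zoo),
               " single models and a traditional stacking baseline")
      metrics <- rbind(compare_models(data, label, zoo, config), metrics)
    }
    test <- data[setdiff(seq_len(nrow(data)), train_rows), , drop = FALSE]
    roc <- roc_points(test[[label]],
                      predict(ensemble, test, type = "prob"))

    stage <- "artifacts"
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(roc, file.path(out_dir, "roc_points.csv"),
                     row.names = FALSE)
    utils::write.csv(contributions, file.path(out_dir, "contributions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(trace_as_list(ensemble$trace),
                         file.path(out_dir, "selection_trace.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(config_snapshot(input, label, normalize, cutoff, config),
                     file.path(out_dir, "config.yaml"))
    saveRDS(ensemble, file.path(out_dir, "ensemble.rds"))
    log_line("done")
    invisible(list(ensemble = ensemble, metrics = metrics,
                   contributions = contributions, out_dir = out_dir))
  }, error = on_fail)
}

#' Evaluate every zoo member plus a traditional stacking baseline
#'
#' Uses the same seeded stratified 8:2 split as [adaptive_stacking()] with
#' the same configuration seed, trains each single model on the training
#' split, and fits a traditional stacking ensemble (no F1 screen, no
#' pruning, logistic-regression meta-learner) for reference.
#'
#' @inheritParams run_pipeline
#' @param data Feature table.
#' @return Data frame with one metrics row per model.
#' @export
compare_models <- function(data, label = "Diabetes_binary",
                           zoo = default_zoo(config$seed),
                           config = selection_config()) {
  y <- check_binary(data[[label]], label)
  set.seed(derive_seed(config$seed, 7L))
  perm <- sample(nrow(data))
  data <- data[perm, , drop = FALSE]
  rownames(data) <- NULL
  in_train <- stratified_split(y[perm], config$train_fraction,
                               derive_seed(config$seed, 13L))
  train <- data[in_train, , drop = FALSE]
  test <- data[!in_train, , drop = FALSE]
  rows <- lapply(names(zoo), function(nm) {
    m <- train_model(zoo[[nm]], train, label)
    p <- predict_proba(m, test)
    as.data.frame(metrics_report(test[[label]], as.integer(p >= 0.5), p,
                                 model = nm))
  })
  trad_cfg <- traditional_stacking_config(
    folds = config$folds, train_fraction = config$train_fraction,
    meta_feature_type = config$meta_feature_type,
    min_per_class = config$min_per_class, seed = config$seed)
  trad <- adaptive_stacking(data, label, zoo, trad_cfg)
  trad_row <- as.data.frame(trad$test_metrics)
  trad_row$Model <- "Stacking"
  do.call(rbind, c(rows, list(trad_row)))
}

trace_as_list <- function(trace) {
  list(
    f1 = as.list(trace$f1),
    cv_accuracy = as.list(trace$cv_accuracy),
    lambda = trace$lambda,
    threshold_mode = if (is.numeric(trace$threshold_mode))
      trace$threshold_mode else as.character(trace$threshold_mode),
    survivors = trace$survivors,
    eliminations = trace$eliminations,
    selected = trace$selected,
    q_matrix = if (!is.null(trace$diversity)) {
      m <- trace$diversity$q
      stats::setNames(lapply(seq_len(nrow(m)), function(i) as.list(m[i, ])),
                      rownames(m))
    },
    q_avg = if (!is.null(trace$diversity)) trace$diversity$q_avg
  )
}

config_snapshot <- function(input, label, normalize, cutoff, config) {
  list(
    input = if (inherits(input, "brfss_config")) {
      list(generator = list(n_samples = input$n_samples,
                            balance = input$balance,
                            noise = input$noise, seed = input$seed,
                            effects = as.list(input$effects)))
    } else list(path = input),
    label = label,
    normalize = normalize,
    attribution_cutoff = cutoff,
    selection = list(
      f1_threshold = if (is.numeric(config$f1_threshold))
        config$f1_threshold else as.character(config$f1_threshold),
      q_cutoff = config$q_cutoff, folds = config$folds,
      train_fraction = config$train_fraction,
      meta_candidates = config$meta_candidates,
      meta_feature_type = config$meta_feature_type,
      seed = config$seed)
  )
}
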