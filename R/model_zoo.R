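# Uniform train/predict registry for the ten pre-selected classifier
# families. Every backend returns positive-class probabilities so the
# stacking layers never need family-specific code.

#' Registered classifier families
#'
#' The registry covers the ten families compared in the reference study:
#' k-nearest neighbours, support vector machine, random forest, logistic
#' regression, decision tree, four gradient-boosting variants and a
#' multilayer perceptron. The boosting variants are all served by the xgboost
#' library configured as the algorithm each family name denotes: `gbdt` is
#' exact greedy depth-wise boosting with shallow trees, `xgboost` the library
#' defaults, `lightgbm` histogram-binned leaf-wise (loss-guide) growth, and
#' `catboost` histogram depth-wise growth with strong L2 regularisation and
#' column subsampling. Backend availability is checked at registry load so a
#' missing library surfaces immediately rather than mid-pipeline.
#'
#' @return A data frame with columns `family`, `backend` (R package used) and
#'   `available` (logical).
#' @export
model_families <- function() {
  fam <- names(zoo_backends)
  pkg <- vapply(zoo_backends, function(b) b$package, character(1))
  data.frame(
    family = fam,
    backend = pkg,
    available = vapply(pkg, requireNamespace, logical(1), quietly = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Specify a classifier
#'
#' @param family One of the registered family keys (see [model_families()]).
#' @param name Unique identifier for the model; defaults to the family key.
#' @param params Named list of hyperparameter overrides merged over the
#'   family defaults.
#' @param seed Integer seed threaded to the backend for reproducibility.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(family, name = family, params = list(), seed = 1L) {
  family <- match.arg(family, names(zoo_backends))
  stopifnot(is.list(params))
  structure(list(name = name, family = family, params = params,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' The default ten-model zoo
#'
#' One spec per registered family, in the order of the reference comparison.
#'
#' @param seed Base seed; each spec gets a distinct seed derived from it.
#' @param params Optional named list of per-family parameter overrides,
#'   e.g. `list(rf = list(ntree = 100))`.
#' @return Named list of `"model_spec"` objects.
#' @export
default_zoo <- function(seed = 1L, params = list()) {
  fams <- names(zoo_backends)
  specs <- lapply(seq_along(fams), function(i) {
    model_spec(fams[i], params = params[[fams[i]]] %||% list(),
               seed = derive_seed(seed, i))
  })
  names(specs) <- fams
  specs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483647)
}

#' Train a classifier from a spec
#'
#' Fits the spec's family on the feature table, seeding the backend so that
#' identical (spec, data) pairs give identical fits.
#'
#' @param spec A `"model_spec"`.
#' @param data Data frame of numeric features plus the binary label column.
#' @param label Name of the label column.
#' @return An object of class `"trained_model"`.
#' @export
train_model <- function(spec, data, label = "Diabetes_binary") {
  stopifnot(inherits(spec, "model_spec"))
  xy <- split_xy(data, label)
  if (length(unique(xy$y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  backend <- zoo_backends[[spec$family]]
  if (!requireNamespace(backend$package, quietly = TRUE))
    stop(sprintf("backend package '%s' for family '%s' is not installed",
                 backend$package, spec$family), call. = FALSE)
  params <- utils::modifyList(backend$defaults, spec$params)
  set.seed(spec$seed)
  fit <- backend$fit(xy$x, xy$y, params)
  structure(list(spec = spec, fit = fit, features = colnames(xy$x),
                 label = label),
            class = "trained_model")
}

#' Positive-class probabilities from a trained model
#'
#' @param model A `"trained_model"`.
#' @param data Data frame containing at least the training features.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, data) {
  stopifnot(inherits(model, "trained_model"))
  x <- feature_matrix(data, model$features)
  backend <- zoo_backends[[model$spec$family]]
  # lazy learners (KNN) resolve ties stochastically at prediction time
  set.seed(derive_seed(model$spec$seed, 997L))
  p <- backend$predict(model$fit, x)
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Hard labels from a trained model
#'
#' @inheritParams predict_proba
#' @param threshold Probability cut for class 1 (label 1 iff p >= threshold).
#' @return Integer vector of 0/1 labels.
#' @export
predict_label <- function(model, data, threshold = 0.5) {
  as.integer(predict_proba(model, data) >= threshold)
}

#' @export
print.trained_model <- function(x, ...) {
  cat("Trained", x$spec$family, "model '", x$spec$name, "' on ",
      length(x$features), " features\n", sep = "")
  invisible(x)
}

split_xy <- function(data, label) {
  if (!label %in% names(data))
    stop(sprintf("label column '%s' not found", label), call. = FALSE)
  y <- check_binary(data[[label]], label)
  x <- feature_matrix(data[setdiff(names(data), label)])
  if (ncol(x) < 1L) stop("no feature columns", call. = FALSE)
  list(x = x, y = y)
}

feature_matrix <- function(data, features = NULL) {
  if (!is.null(features)) {
    missing <- setdiff(features, names(data))
    if (length(missing))
      stop("missing feature columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    data <- data[features]
  }
  if (!all(vapply(data, is.numeric, logical(1))))
    stop("all feature columns must be numeric", call. = FALSE)
  as.matrix(data)
}

xgb_fit <- function(x, y, params) {
  nrounds <- params$nrounds
  params$nrounds <- NULL
  params <- utils::modifyList(
    list(objective = "binary:logistic", nthread = 1L), params)
  xgboost::xgb.train(params = params,
                     data = xgboost::xgb.DMatrix(x, label = y),
                     nrounds = nrounds, verbose = 0)
}

xgb_predict <- function(fit, x) predict(fit, xgboost::xgb.DMatrix(x))

zoo_backends <- list(
  knn = list(
    package = "class",
    defaults = list(k = 5L),
    fit = function(x, y, params) list(x = x, y = y, k = params$k),
    predict = function(fit, x) {
      cl <- class::knn(train = fit$x, test = x, cl = factor(fit$y, c(0, 1)),
                       k = fit$k, prob = TRUE)
      p_win <- attr(cl, "prob")
      ifelse(cl == "1", p_win, 1 - p_win)
    }
  ),
  svm = list(
    package = "e1071",
    defaults = list(kernel = "radial", cost = 1),
    fit = function(x, y, params) {
      e1071::svm(x, factor(y, c(0, 1)), kernel = params$kernel,
                 cost = params$cost, probability = TRUE, scale = FALSE)
    },
    predict = function(fit, x) {
      attr(predict(fit, x, probability = TRUE), "probabilities")[, "1"]
    }
  ),
  rf = list(
    package = "randomForest",
    defaults = list(ntree = 300L),
    fit = function(x, y, params) {
      randomForest::randomForest(x, factor(y, c(0, 1)), ntree = params$ntree)
    },
    predict = function(fit, x) predict(fit, x, type = "prob")[, "1"]
  ),
  lr = list(
    package = "stats",
    defaults = list(),
    fit = function(x, y, params) {
      df <- as.data.frame(x)
      df$.y <- y
      # separation warnings are expected on strongly separable data
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    predict = function(fit, x) {
      predict(fit, newdata = as.data.frame(x), type = "response")
    }
  ),
  dt = list(
    package = "rpart",
    defaults = list(cp = 0.01, minsplit = 20L),
    fit = function(x, y, params) {
      df <- as.data.frame(x)
      df$.y <- factor(y, c(0, 1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = params$cp,
                                                  minsplit = params$minsplit))
    },
    predict = function(fit, x) {
      predict(fit, newdata = as.data.frame(x), type = "prob")[, "1"]
    }
  ),
  gbdt = list(
    package = "xgboost",
    defaults = list(nrounds = 100L, max_depth = 3L, eta = 0.1,
                    tree_method = "exact"),
    fit = xgb_fit, predict = xgb_predict
  ),
  xgboost = list(
    package = "xgboost",
    defaults = list(nrounds = 100L, max_depth = 6L, eta = 0.3),
    fit = xgb_fit, predict = xgb_predict
  ),
  lightgbm = list(
    package = "xgboost",
    defaults = list(nrounds = 100L, eta = 0.1, tree_method = "hist",
                    grow_policy = "lossguide", max_leaves = 31L,
                    max_depth = 0L, max_bin = 255L),
    fit = xgb_fit, predict = xgb_predict
  ),
  catboost = list(
    package = "xgboost",
    defaults = list(nrounds = 150L, eta = 0.1, tree_method = "hist",
                    grow_policy = "depthwise", max_depth = 6L,
                    lambda = 3, colsample_bytree = 0.8),
    fit = xgb_fit, predict = xgb_predict
  ),
  mlp = list(
    package = "nnet",
    defaults = list(size = 100L, decay = 1e-4, maxit = 200L),
    fit = function(x, y, params) {
      nnet::nnet(x, y, size = params$size, decay = params$decay,
                 maxit = params$maxit, entropy = TRUE, trace = FALSE,
                 MaxNWts = 100000L)
    },
    predict = function(fit, x) as.numeric(predict(fit, x))
  )
)
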