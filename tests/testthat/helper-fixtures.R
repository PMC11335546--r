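# Shared fixtures, all generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-feature gaussian blobs, linearly separable with the given margin.
make_blob <- function(n = 160, margin = 2, seed = 1, label = "y") {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  out <- data.frame(
    f1 = stats::rnorm(n, mean = margin * (y - 0.5)),
    f2 = stats::rnorm(n, mean = -margin * (y - 0.5))
  )
  out[[label]] <- y
  out[sample(n), , drop = FALSE]
}

# Compact survey schema (subset of features) for fast generator-backed tests.
small_schema <- function() {
  s <- brfss_schema()
  s[s$name %in% c("HighBP", "BMI", "GenHlth", "Age", "Smoker", "Fruits"), ]
}

small_config <- function(n = 400, effects = c(HighBP = 1.5, BMI = 1.2,
                                              GenHlth = 1.8, Age = 0.8),
                         seed = 1) {
  brfss_config(n_samples = n, effects = effects, schema = small_schema(),
               seed = seed)
}

# Fast zoo for stacking tests: cheap families with reduced capacity.
fast_zoo <- function(seed = 1, families = c("lr", "dt", "knn", "gbdt")) {
  zoo <- default_zoo(seed, params = list(
    rf = list(ntree = 50L),
    gbdt = list(nrounds = 25L),
    xgboost = list(nrounds = 25L),
    lightgbm = list(nrounds = 25L),
    catboost = list(nrounds = 25L),
    mlp = list(size = 4L, maxit = 60L)
  ))
  zoo[families]
}

# Ten cross-validated F1 values as printed in the reference comparison table.
reference_f1 <- c(knn = 0.7137, svm = 0.7625, rf = 0.7472, lr = 0.7466,
                  dt = 0.7338, gbdt = 0.7628, xgboost = 0.7593,
                  lightgbm = 0.7645, catboost = 0.7637, mlp = 0.7550)

# O(n^2) pairwise-comparison AUC oracle (ties count one half).
auc_pairwise_oracle <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive interventional Shapley oracle: for sample x, feature i,
# phi_i = sum over subsets S of the other features of
#         w(S) * (v(S + i) - v(S)),  v(S) = mean_b f(x_S, b_rest)
# with the background drawn from the training table.
shapley_oracle <- function(predict_fun, x_row, background) {
  p <- length(x_row)
  feats <- seq_len(p)
  v_cache <- new.env()
  value <- function(S) {
    key <- paste0("s", paste(S, collapse = ","))
    if (!is.null(v_cache[[key]])) return(v_cache[[key]])
    mod <- background
    for (j in S) mod[, j] <- x_row[[j]]
    v <- mean(predict_fun(as.matrix(mod)))
    v_cache[[key]] <- v
    v
  }
  phi <- numeric(p)
  for (i in feats) {
    others <- setdiff(feats, i)
    for (m in 0:length(others)) {
      subsets <- if (m == 0) list(integer(0)) else
        utils::combn(others, m, simplify = FALSE)
      w <- factorial(m) * factorial(p - m - 1) / factorial(p)
      for (S in subsets)
        phi[i] <- phi[i] + w * (value(sort(c(S, i))) - value(S))
    }
  }
  phi
}
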