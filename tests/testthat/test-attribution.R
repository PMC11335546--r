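test_that("attribution model is deterministic and needs both classes", {
  cfg <- small_config(n = 300, seed = 6)
  tab <- simulate_brfss(cfg)
  m1 <- fit_attribution_model(tab, seed = 11)
  m2 <- fit_attribution_model(tab, seed = 11)
  expect_equal(contribution_summary(m1, tab), contribution_summary(m2, tab))

  bad <- tab
  bad$Diabetes_binary <- 0L
  expect_error(fit_attribution_model(bad), "both classes")
})

test_that("local accuracy: baseline plus attributions equals the margin", {
  cfg <- small_config(n = 250, seed = 2)
  tab <- simulate_brfss(cfg)
  m <- fit_attribution_model(tab, seed = 4)
  sv <- shap_values(m, tab)
  margin <- predict(m$booster,
                    xgboost::xgb.DMatrix(as.matrix(tab[m$features])),
                    outputmargin = TRUE)
  reconstructed <- attr(sv, "baseline") + rowSums(sv)
  expect_equal(reconstructed, margin, tolerance = 1e-5)
})

test_that("tree attributions equal the exhaustive Shapley oracle on an additive ensemble", {
  # Depth-1 trees with unit-hessian loss: the cover-weighted tree
  # expectations coincide with uniform training-background expectations, so
  # the interventional Shapley value is recovered exactly.
  set.seed(2)
  n <- 100
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  d$y <- as.integer(d$a + 0.5 * d$b + rnorm(n, 0, 0.5) > 0)
  m <- fit_attribution_model(
    d, label = "y",
    params = list(nrounds = 30, max_depth = 1, eta = 0.3,
                  objective = "reg:squarederror"),
    seed = 3)
  sv <- shap_values(m, d)
  predict_fun <- function(x)
    predict(m$booster, xgboost::xgb.DMatrix(x), outputmargin = TRUE)
  bg <- as.data.frame(d[, m$features])
  for (i in c(1, 7, 50)) {
    phi <- shapley_oracle(predict_fun, d[i, m$features], bg)
    expect_equal(unname(sv[i, ]), phi, tolerance = 1e-5)
  }
})

test_that("single-split tree attributes its output shift to the split feature", {
  set.seed(9)
  d <- data.frame(a = rnorm(150))
  d$y <- as.integer(d$a > 0)
  m <- fit_attribution_model(d, label = "y",
                             params = list(nrounds = 1L, max_depth = 1L,
                                           eta = 1),
                             seed = 1)
  sv <- shap_values(m, d)
  margin <- predict(m$booster, xgboost::xgb.DMatrix(as.matrix(d["a"])),
                    outputmargin = TRUE)
  expect_equal(as.numeric(sv[, "a"]), margin - attr(sv, "baseline"),
               tolerance = 1e-6)
})

test_that("null labels give small contributions; planted signal dominates", {
  set.seed(5)
  null_tab <- as.data.frame(matrix(rbinom(600 * 5, 1, 0.5), ncol = 5))
  null_tab$y <- rbinom(600, 1, 0.5)
  m_null <- fit_attribution_model(null_tab, label = "y", seed = 1)
  c_null <- contribution_summary(m_null, null_tab)
  expect_true(all(c_null$mean_abs_contribution >= 0))
  expect_lt(max(c_null$mean_abs_contribution), 0.4)

  sig_tab <- null_tab
  set.seed(6)
  sig_tab$y <- as.integer(runif(600) < plogis(3 * (sig_tab$V1 - 0.5)))
  m_sig <- fit_attribution_model(sig_tab, label = "y", seed = 1)
  c_sig <- contribution_summary(m_sig, sig_tab)
  expect_identical(c_sig$feature[1], "V1")
  expect_gt(c_sig$mean_abs_contribution[1],
            3 * max(c_null$mean_abs_contribution))
})

test_that("a feature equal to the label is ranked first", {
  set.seed(12)
  d <- data.frame(noise1 = rnorm(200), noise2 = rnorm(200))
  d$y <- rbinom(200, 1, 0.5)
  d$leak <- d$y
  m <- fit_attribution_model(d, label = "y", seed = 2)
  cs <- contribution_summary(m, d)
  expect_identical(cs$feature[1], "leak")
})

test_that("duplicated feature columns share the original's attribution mass", {
  set.seed(7)
  d <- data.frame(a = rnorm(400), b = rnorm(400))
  d$y <- as.integer(d$a + rnorm(400, 0, 0.3) > 0)
  single <- contribution_summary(fit_attribution_model(d, label = "y",
                                                       seed = 2), d)
  d2 <- d
  d2$a2 <- d2$a
  d2 <- d2[, c("a", "a2", "b", "y")]
  dup <- contribution_summary(fit_attribution_model(d2, label = "y",
                                                    seed = 2), d2)
  mass <- sum(dup$mean_abs_contribution[dup$feature %in% c("a", "a2")])
  expect_equal(mass, single$mean_abs_contribution[single$feature == "a"],
               tolerance = 0.05)
})

test_that("feature filtering respects the cutoff, keeps the label, and preserves order", {
  fake <- structure(data.frame(feature = c("A", "B"),
                               mean_abs_contribution = c(0.5, 0.05),
                               rank = 1:2, stringsAsFactors = FALSE),
                    class = c("contribution_summary", "data.frame"))
  d <- data.frame(B = 1:4, A = 5:8, y = c(0, 1, 0, 1))
  kept <- filter_features(fake, d, cutoff = 0.1, label = "y")
  expect_identical(names(kept), c("A", "y"))
  expect_identical(names(filter_features(fake, d, cutoff = 0, label = "y")),
                   c("B", "A", "y"))  # identity, original order
  expect_error(filter_features(fake, d, cutoff = 10, label = "y"),
               "removed all features")
  expect_identical(formals(filter_features)$cutoff, 0.1)

  # idempotence and monotonicity
  once <- filter_features(fake, d, cutoff = 0.1, label = "y")
  twice <- filter_features(fake, once, cutoff = 0.1, label = "y")
  expect_identical(once, twice)
  cuts <- c(0, 0.04, 0.1, 0.4)
  kept_sets <- lapply(cuts, function(ct)
    names(filter_features(fake, d, cutoff = ct, label = "y")))
  for (i in seq_len(length(cuts) - 1L))
    expect_true(all(kept_sets[[i + 1L]] %in% kept_sets[[i]]))
})
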