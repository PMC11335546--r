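# Synthetic survey generator emulating the 21-feature BRFSS
# diabetes-health-indicators schema, so every other module is testable
# without the external download. Labels are drawn first and features are
# drawn conditional on the label through a latent-shift model, which makes
# per-feature effect sizes directly controllable.

#' Feature schema of the emulated health survey
#'
#' The 21 features of the diabetes-health-indicators table: 14 binary risk
#' indicators, six ordinal scales and one continuous measure (BMI). Column
#' names follow the public dataset's header conventions so real data drops in
#' unchanged.
#'
#' @return Data frame with columns `name`, `type` (`binary`, `ordinal`,
#'   `continuous`), `min`, `max` and `base_rate` (binary features only).
#' @export
brfss_schema <- function() {
  bin <- function(name, rate) data.frame(name = name, type = "binary",
                                         min = 0, max = 1, base_rate = rate)
  ord <- function(name, lo, hi) data.frame(name = name, type = "ordinal",
                                           min = lo, max = hi, base_rate = NA)
  rbind(
    bin("HighBP", 0.45), bin("HighChol", 0.45), bin("CholCheck", 0.95),
    data.frame(name = "BMI", type = "continuous", min = 12, max = 98,
               base_rate = NA),
    bin("Smoker", 0.45), bin("Stroke", 0.06),
    bin("HeartDiseaseorAttack", 0.12), bin("PhysActivity", 0.72),
    bin("Fruits", 0.62), bin("Veggies", 0.79),
    bin("HvyAlcoholConsump", 0.05), bin("AnyHealthcare", 0.95),
    bin("NoDocbcCost", 0.09),
    ord("GenHlth", 1, 5), ord("MentHlth", 0, 30), ord("PhysHlth", 0, 30),
    bin("DiffWalk", 0.2), bin("Sex", 0.44),
    ord("Age", 1, 13), ord("Education", 1, 6), ord("Income", 1, 8)
  )
}

# Default class-separation effects (latent/log-odds scale), mimicking the
# directions and relative strengths of known diabetes risk associations:
# general health, BMI, age and blood pressure dominate; the care-access
# indicators (CholCheck, AnyHealthcare, NoDocbcCost) and alcohol carry
# little signal, as in the reference survey.
default_effects <- c(
  HighBP = 1.1, HighChol = 0.7, CholCheck = 0.05, BMI = 1.0, Smoker = 0.25,
  Stroke = 0.45, HeartDiseaseorAttack = 0.65, PhysActivity = -0.35,
  Fruits = -0.1, Veggies = -0.12, HvyAlcoholConsump = -0.25,
  AnyHealthcare = 0.04, NoDocbcCost = 0.08, GenHlth = 1.3, MentHlth = 0.15,
  PhysHlth = 0.35, DiffWalk = 0.75, Sex = 0.12, Age = 0.95,
  Education = -0.35, Income = -0.55
)

#' Generator configuration
#'
#' @param n_samples Number of rows to draw (>= 2).
#' @param balance Probability of the positive class, in (0, 1); the reference
#'   dataset is balanced, hence the 0.5 default.
#' @param effects Named vector of per-feature class-separation effects on the
#'   latent scale (log-odds for binary features; latent standard-deviation
#'   shift for ordinal/continuous features). Positive values make the feature
#'   higher among cases. Defaults emulate known diabetes risk associations.
#' @param noise Latent noise standard deviation (> 0); larger values weaken
#'   every feature-label association.
#' @param schema Feature schema data frame, by default [brfss_schema()].
#' @param label Name of the label column in generated tables.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @return An object of class `"brfss_config"`.
#' @export
brfss_config <- function(n_samples = 2000L, balance = 0.5,
                         effects = default_effects, noise = 1,
                         schema = brfss_schema(),
                         label = "Diabetes_binary", seed = 1L) {
  stopifnot(n_samples >= 2L, balance > 0, balance < 1, noise > 0)
  if (!all(c("name", "type", "min", "max") %in% names(schema)))
    stop("schema must have columns name, type, min, max", call. = FALSE)
  if (any(schema$type == "ordinal" & schema$max - schema$min < 1))
    stop("ordinal features need at least 2 levels", call. = FALSE)
  eff <- stats::setNames(rep(0, nrow(schema)), schema$name)
  if (length(effects)) {
    if (is.null(names(effects)) && length(effects) == nrow(schema))
      names(effects) <- schema$name
    unknown <- setdiff(names(effects), schema$name)
    if (length(unknown))
      stop("effects for unknown features: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    eff[names(effects)] <- effects
  }
  structure(list(n_samples = as.integer(n_samples), balance = balance,
                 effects = eff, noise = noise, schema = schema,
                 label = label, seed = as.integer(seed)),
            class = "brfss_config")
}

#' Simulate a health-survey feature table
#'
#' Draws labels at the configured class balance, then each feature
#' conditional on the label: binary indicators from a logistic model whose
#' log-odds shift by the feature's effect between classes; ordinal scales by
#' binning a label-shifted latent normal at equal-probability cut points; BMI
#' from a label-shifted log-normal clipped to its range.
#'
#' @param config A `"brfss_config"`.
#' @return A data frame with one column per schema feature plus the binary
#'   label column; no missing values.
#' @examples
#' tab <- simulate_brfss(brfss_config(n_samples = 100, seed = 7))
#' dim(tab)  # 100 x 22
#' @export
simulate_brfss <- function(config) {
  stopifnot(inherits(config, "brfss_config"))
  set.seed(config$seed)
  n <- config$n_samples
  y <- stats::rbinom(n, 1L, config$balance)
  shift <- (y - 0.5)  # +0.5 for cases, -0.5 for controls
  cols <- vector("list", nrow(config$schema))
  for (j in seq_len(nrow(config$schema))) {
    s <- config$schema[j, ]
    eff <- config$effects[[s$name]]
    cols[[j]] <- switch(
      s$type,
      binary = {
        base <- if (is.na(s$base_rate)) 0.5 else s$base_rate
        p <- stats::plogis(stats::qlogis(base) + eff * shift / config$noise)
        stats::rbinom(n, 1L, p)
      },
      ordinal = {
        z <- stats::rnorm(n, mean = eff * shift, sd = config$noise)
        levels <- seq(s$min, s$max)
        # equal-probability bins on the null latent scale
        cuts <- stats::qnorm(seq_len(length(levels) - 1L) / length(levels),
                             sd = config$noise)
        levels[findInterval(z, cuts) + 1L]
      },
      continuous = {
        z <- stats::rnorm(n, mean = eff * shift, sd = config$noise)
        # log-normal around BMI ~ 28 with ~20% spread on the log scale
        v <- exp(log(28) + 0.2 * z / config$noise)
        round(pmin(pmax(v, s$min), s$max), 1)
      },
      stop("unknown feature type: ", s$type, call. = FALSE)
    )
  }
  out <- as.data.frame(stats::setNames(cols, config$schema$name))
  out[[config$label]] <- y
  out
}

#' Write a simulated table as CSV
#'
#' Plain CSV with the public dataset's header names, so files are
#' interchangeable with the real download.
#'
#' @param data A feature table (from [simulate_brfss()] or compatible).
#' @param path Output file path.
#' @export
write_survey_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check that attribution ranking recovers planted effect sizes
#'
#' Generates a table from the configuration, fits the gradient-boosting
#' attribution model, and correlates each feature's absolute planted effect
#' with its mean absolute Shapley contribution. A well-behaved generator and
#' attribution stack give a clearly positive rank correlation.
#'
#' @param config A `"brfss_config"` with at least two distinct nonzero
#'   effects.
#' @param seed Seed for the attribution model fit.
#' @return Spearman rank correlation between |effect| and contribution;
#'   `NA` (with a warning) when all |effects| are tied so ranks are
#'   undefined.
#' @export
effect_recovery_check <- function(config, seed = 1L) {
  stopifnot(inherits(config, "brfss_config"))
  if (sum(config$effects != 0) < 2L)
    stop("need at least two nonzero effects", call. = FALSE)
  tab <- simulate_brfss(config)
  model <- fit_attribution_model(tab, label = config$label, seed = seed)
  cs <- contribution_summary(model, tab)
  eff <- abs(config$effects[cs$feature])
  if (length(unique(eff)) < 2L) {
    warning("all |effects| tied; rank correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(eff, cs$mean_abs_contribution, method = "spearman")
}
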