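#' Declare a single cohort feature
#'
#' A feature specification fixes a feature's name, type, sampling
#' distribution and its effect on the log-odds of the binary outcome in the
#' cohort generator's logistic risk model.
#'
#' @param name feature name (unique within a cohort spec).
#' @param kind one of `"continuous"`, `"categorical"`, `"binary"`.
#' @param levels ordered character vector of category labels (categorical
#'   only). The first level is the reference: its effect is fixed at 0.
#' @param location,scale mean and standard deviation of the sampling normal
#'   (continuous only); `scale` must be positive.
#' @param lower,upper truncation bounds for the continuous sampler
#'   (default untruncated).
#' @param probs level probabilities (categorical only); must sum to 1.
#' @param rate Bernoulli success probability (binary only).
#' @param effect log-odds coefficient(s): a scalar for continuous/binary
#'   features, or one value per level (first element 0) for categorical
#'   features.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(name, kind = c("continuous", "categorical", "binary"),
                         levels = NULL, location = 0, scale = 1,
                         lower = -Inf, upper = Inf,
                         probs = NULL, rate = 0.5, effect = 0) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 2L)
      stop("categorical feature '", name, "' needs at least 2 levels")
    if (anyDuplicated(levels)) stop("duplicate levels in feature '", name, "'")
    if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
    if (length(probs) != length(levels))
      stop("probs must have one entry per level for feature '", name, "'")
    if (any(probs < 0) || any(probs > 1) || abs(sum(probs) - 1) > 1e-12)
      stop("level probabilities of '", name,
           "' must lie in [0,1] and sum to 1 within 1e-12")
    if (length(effect) == 1L && effect == 0) effect <- rep(0, length(levels))
    if (length(effect) != length(levels))
      stop("categorical feature '", name, "' needs one effect per level")
    if (effect[1L] != 0)
      stop("first (reference) level effect of '", name, "' must be 0")
  } else {
    if (length(effect) != 1L)
      stop(kind, " feature '", name, "' takes a single effect coefficient")
    levels <- NULL
    probs <- NULL
  }
  if (kind == "continuous") {
    if (!is.numeric(scale) || scale <= 0)
      stop("continuous feature '", name, "' needs scale > 0")
    if (lower >= upper) stop("lower must be < upper for feature '", name, "'")
  }
  if (kind == "binary" && (rate < 0 || rate > 1))
    stop("binary rate of '", name, "' must lie in [0,1]")
  structure(
    list(name = name, kind = kind, levels = levels,
         location = location, scale = scale, lower = lower, upper = upper,
         probs = probs, rate = rate, effect = as.numeric(effect)),
    class = "feature_spec"
  )
}

#' Declare a synthetic cohort
#'
#' Combines feature specifications with a logistic outcome model:
#' `P(Y = 1 | x) = plogis(intercept + sum(effects * encoded x))`.
#'
#' @param features list of [feature_spec()] objects with unique names.
#' @param intercept log-odds intercept; `NA` (the default) means "calibrate
#'   to `target_prevalence` at generation time" (see
#'   [calibrate_intercept()]).
#' @param target_prevalence desired marginal case proportion, strictly in
#'   (0, 1).
#' @param n number of rows to generate (>= 2).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(features, intercept = NA_real_,
                        target_prevalence = 0.006, n = 10000L) {
  stopifnot(is.list(features), length(features) >= 1L)
  if (!all(vapply(features, inherits, logical(1), "feature_spec")))
    stop("features must be a list of feature_spec objects")
  nms <- vapply(features, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("feature names must be unique")
  if (!is.numeric(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1)
    stop("target_prevalence must lie strictly in (0, 1)")
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  names(features) <- nms
  structure(
    list(features = features, intercept = intercept,
         target_prevalence = target_prevalence, n = as.integer(n)),
    class = "cohort_spec"
  )
}

# schema: the minimal per-feature type metadata every cohort carries,
# independent of whether it came from a generator spec or a CSV sidecar
schema_from_spec <- function(spec) {
  lapply(spec$features, function(f)
    list(name = f$name, kind = f$kind, levels = f$levels))
}

new_cohort <- function(data, outcome, schema, spec = NULL, seed = NULL,
                       source = "synthetic", row_id = NULL) {
  stopifnot(is.data.frame(data), nrow(data) > 0L)
  if (anyDuplicated(names(data))) stop("cohort column names must be unique")
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(data)) stop("outcome length must match rows")
  if (!all(outcome %in% c(0L, 1L))) stop("outcome must contain only 0/1")
  for (s in schema) {
    if (s$kind == "categorical") {
      vals <- as.character(data[[s$name]])
      bad <- setdiff(unique(vals), s$levels)
      if (length(bad))
        stop("feature '", s$name, "' contains undeclared level(s): ",
             paste(bad, collapse = ", "))
      data[[s$name]] <- factor(vals, levels = s$levels)
    }
  }
  structure(
    list(data = data, outcome = outcome, schema = schema, spec = spec,
         seed = seed, source = source,
         row_id = row_id %||% seq_len(nrow(data))),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d rows x %d features; %d cases (%.3f%%); source: %s\n",
              nrow(x$data), ncol(x$data), sum(x$outcome),
              100 * mean(x$outcome), x$source))
  invisible(x)
}

#' Number of rows in a cohort
#' @param cohort a `cohort` object.
#' @return integer row count.
#' @export
cohort_size <- function(cohort) nrow(cohort$data)

# linear predictor WITHOUT the intercept, vectorized over rows
linear_predictor <- function(data, spec) {
  lp <- numeric(nrow(data))
  for (f in spec$features) {
    x <- data[[f$name]]
    if (is.null(x)) stop("missing feature column '", f$name, "'")
    if (f$kind == "categorical") {
      xc <- as.character(x)
      idx <- match(xc, f$levels)
      if (anyNA(idx)) {
        bad <- unique(xc[is.na(idx)])[1L]
        stop("feature '", f$name, "': unknown category level '", bad, "'")
      }
      lp <- lp + f$effect[idx]
    } else {
      lp <- lp + f$effect * as.numeric(x)
    }
  }
  lp
}

#' Outcome probability under a cohort spec's logistic risk model
#'
#' @param feature_row a one-or-more-row data frame conforming to the spec's
#'   feature specifications.
#' @param spec a [cohort_spec()]; its `intercept` must be set (not `NA`).
#' @return numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
risk_probability <- function(feature_row, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.na(spec$intercept))
    stop("spec intercept is NA; run calibrate_intercept() first")
  logistic(spec$intercept + linear_predictor(feature_row, spec))
}

# sample the feature table only (no outcome); caller manages the RNG seed
sample_features <- function(spec, n) {
  cols <- lapply(spec$features, function(f) {
    switch(f$kind,
      continuous = {
        # inverse-CDF sampling of a (possibly truncated) normal
        plo <- stats::pnorm(f$lower, f$location, f$scale)
        phi <- stats::pnorm(f$upper, f$location, f$scale)
        u <- stats::runif(n, plo, phi)
        stats::qnorm(u, f$location, f$scale)
      },
      categorical = factor(sample(f$levels, n, replace = TRUE, prob = f$probs),
                           levels = f$levels),
      binary = stats::rbinom(n, 1L, f$rate)
    )
  })
  as.data.frame(cols, optional = TRUE, check.names = FALSE)
}

#' Calibrate the risk-model intercept to a target prevalence
#'
#' Finds, by bisection, the log-odds intercept at which the Monte-Carlo mean
#' of [risk_probability()] over a large seeded feature sample matches the
#' spec's `target_prevalence`. The mean risk is strictly increasing in the
#' intercept, so bisection is guaranteed to converge.
#'
#' @param spec a [cohort_spec()].
#' @param tolerance maximum allowed |realized mean risk - target| (> 0).
#' @param seed integer seed for the Monte-Carlo feature sample.
#' @param n_mc Monte-Carlo sample size (default 1e5).
#' @param max_iter bisection iteration cap.
#' @return the calibrated intercept (log-odds scalar).
#' @export
calibrate_intercept <- function(spec, tolerance = 1e-4, seed = 1L,
                                n_mc = 1e5, max_iter = 200L) {
  stopifnot(inherits(spec, "cohort_spec"), tolerance > 0)
  lp <- withr::with_seed(seed, linear_predictor(sample_features(spec, n_mc), spec))
  mean_risk <- function(b) mean(logistic(b + lp))
  lo <- -40; hi <- 40
  if (mean_risk(lo) > spec$target_prevalence ||
      mean_risk(hi) < spec$target_prevalence)
    stop("target prevalence not bracketed by intercepts in [-40, 40]")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- mean_risk(mid)
    if (abs(r - spec$target_prevalence) <= tolerance) return(mid)
    if (r < spec$target_prevalence) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "intercept calibration did not converge in %d iterations; bracket [%g, %g]",
    max_iter, lo, hi))
}

#' Generate a synthetic cohort
#'
#' Samples `spec$n` rows independently from the feature distributions and
#' draws the binary outcome as Bernoulli([risk_probability()]). Identical
#' `(spec, seed)` pairs yield bit-identical cohorts. If the spec's intercept
#' is `NA` it is first calibrated to the target prevalence with a sub-seed
#' derived from `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return a `cohort` object.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (f in spec$features) {
    if (f$kind == "continuous" && f$scale <= 1e-12 && any(f$effect != 0))
      warning("feature '", f$name,
              "' is informative but has (near) zero variance")
  }
  if (is.na(spec$intercept))
    spec$intercept <- calibrate_intercept(
      spec, seed = derive_seed(seed, "calibrate"))
  dat <- withr::with_seed(seed, {
    d <- sample_features(spec, spec$n)
    p <- logistic(spec$intercept + linear_predictor(d, spec))
    list(features = d, outcome = stats::rbinom(spec$n, 1L, p))
  })
  new_cohort(dat$features, dat$outcome, schema_from_spec(spec),
             spec = spec, seed = seed, source = "synthetic")
}

#' Default synthetic primary-care lung-cancer cohort specification
#'
#' A cohort spec with the structure of a primary-care lung-cancer risk
#' dataset: one continuous feature (age, truncated normal on a 30-90
#' screening-age range), one nine-level categorical smoking status/intensity
#' feature (Ex Unknown, Ex Light, Ex Moderate, Ex Heavy, Current Unknown,
#' Current Light, Current Moderate, Current Heavy, Missing — "Missing" is an
#' ordinary category, not a missing value), 26 binary comorbidity/symptom
#' flags, and a target case prevalence of 0.6%. Effect sizes are
#' illustrative: positive log-odds contributions on age, current-heavy
#' smoking, and a plausible subset of the flags (e.g. haemoptysis, COPD,
#' family history of lung cancer); the remaining flags are noise features.
#'
#' @param n number of rows the spec will generate (default 1e5).
#' @param target_prevalence marginal case proportion (default 0.006).
#' @return a [cohort_spec()].
#' @export
lung_cohort_spec <- function(n = 1e5, target_prevalence = 0.006) {
  smoking_levels <- c("Ex Unknown", "Ex Light", "Ex Moderate", "Ex Heavy",
                      "Current Unknown", "Current Light", "Current Moderate",
                      "Current Heavy", "Missing")
  # mild gradient in smoking intensity, strongest for current heavy smokers
  smoking_effect <- c(0, 0.10, 0.25, 0.45, 0.50, 0.60, 0.85, 1.20, 0.05)
  smoking_probs <- c(0.10, 0.10, 0.08, 0.07, 0.08, 0.12, 0.12, 0.13, 0.20)

  flags <- c(
    bronchiectasis            = 0.40,
    cerebrovascular_disease   = 0.10,
    chronic_kidney_disease    = 0.05,
    copd_emphysema            = 0.80,
    diabetes_end_stage        = 0.10,
    diabetes_no_end_stage     = 0.05,
    family_history_cancer     = 0.30,
    family_history_lung_cancer = 0.70,
    idiopathic_fibrosis       = 0.50,
    lower_respiratory_tract_infection = 0.45,
    bmi_low                   = 0.35,
    peptic_ulcer              = 0.00,
    alcohol_heavy             = 0.15,
    peripheral_vascular_disease = 0.10,
    radiotherapy_history      = 0.25,
    breast_cancer_history     = 0.10,
    bladder_cancer_history    = 0.15,
    head_neck_cancer_history  = 0.30,
    thyroid_cancer_history    = 0.00,
    dyspnoea                  = 0.55,
    haemoptysis               = 1.50,
    cough                     = 0.50,
    sputum_production         = 0.40,
    back_pain                 = 0.10,
    blood_test_performed      = 0.20,
    night_sweats              = 0.05
  )
  rates <- c(
    bronchiectasis = 0.01, cerebrovascular_disease = 0.04,
    chronic_kidney_disease = 0.05, copd_emphysema = 0.06,
    diabetes_end_stage = 0.02, diabetes_no_end_stage = 0.07,
    family_history_cancer = 0.15, family_history_lung_cancer = 0.04,
    idiopathic_fibrosis = 0.005, lower_respiratory_tract_infection = 0.10,
    bmi_low = 0.08, peptic_ulcer = 0.03, alcohol_heavy = 0.12,
    peripheral_vascular_disease = 0.03, radiotherapy_history = 0.01,
    breast_cancer_history = 0.03, bladder_cancer_history = 0.01,
    head_neck_cancer_history = 0.005, thyroid_cancer_history = 0.005,
    dyspnoea = 0.09, haemoptysis = 0.004, cough = 0.20,
    sputum_production = 0.08, back_pain = 0.12, blood_test_performed = 0.45,
    night_sweats = 0.03
  )

  features <- c(
    list(
      feature_spec("age", "continuous", location = 60, scale = 12,
                   lower = 30, upper = 90, effect = 0.05),
      feature_spec("smoking_status", "categorical", levels = smoking_levels,
                   probs = smoking_probs, effect = smoking_effect)
    ),
    lapply(names(flags), function(nm)
      feature_spec(nm, "binary", rate = rates[[nm]], effect = flags[[nm]]))
  )
  cohort_spec(features, intercept = NA_real_,
              target_prevalence = target_prevalence, n = n)
}
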