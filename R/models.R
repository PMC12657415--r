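#' One-hot design matrix for a cohort feature table
#'
#' Continuous and binary features map to single numeric columns; each
#' categorical feature maps to indicator columns for its non-reference
#' levels (first declared level is the baseline), named `feature=level`.
#' All models and the risk model share this encoding, so explainers and
#' classifiers see the same design.
#'
#' @param data feature data frame.
#' @param schema cohort schema (list of `name`/`kind`/`levels` entries).
#' @return numeric matrix with one row per input row.
#' @export
encode_design <- function(data, schema) {
  cols <- list()
  for (s in schema) {
    x <- data[[s$name]]
    if (is.null(x)) stop("missing feature column '", s$name, "'")
    if (s$kind == "categorical") {
      xc <- as.character(x)
      bad <- setdiff(unique(xc), s$levels)
      if (length(bad))
        stop("feature '", s$name, "': unknown category level '", bad[1L], "'")
      for (lv in s$levels[-1L])
        cols[[paste0(s$name, "=", lv)]] <- as.numeric(xc == lv)
    } else {
      cols[[s$name]] <- as.numeric(x)
    }
  }
  do.call(cbind, cols)
}

#' Construct a model adapter
#'
#' A model adapter is the package's black-box contract: `fit_model()` trains
#' it on a cohort and the fitted object maps any conforming feature table to
#' per-row probabilities of the positive class in `[0, 1]`, deterministically
#' at fixed fitted state.
#'
#' @param label adapter name.
#' @param fit_fn `function(X, y, seed)` returning a fitted state; `X` is the
#'   encoded design matrix, `y` the 0/1 outcome.
#' @param predict_fn `function(state, X)` returning probabilities.
#' @param params named list of constructor arguments, recorded in manifests.
#' @return an object of class `model_adapter`.
#' @export
model_adapter <- function(label, fit_fn, predict_fn, params = list()) {
  structure(list(label = label, fit_fn = fit_fn, predict_fn = predict_fn,
                 params = params),
            class = "model_adapter")
}

#' Fit a model adapter on a cohort
#'
#' @param adapter a [model_adapter()].
#' @param cohort training `cohort`.
#' @param seed integer seed (models with stochastic training consume it).
#' @return an object of class `fitted_model`.
#' @export
fit_model <- function(adapter, cohort, seed = 1L) {
  stopifnot(inherits(adapter, "model_adapter"), inherits(cohort, "cohort"))
  X <- encode_design(cohort$data, cohort$schema)
  state <- adapter$fit_fn(X, cohort$outcome, seed)
  structure(list(adapter = adapter, state = state, schema = cohort$schema,
                 train_cohort = cohort, seed = seed),
            class = "fitted_model")
}

#' Predict positive-class probabilities
#'
#' @param model a `fitted_model`.
#' @param data feature data frame conforming to the training schema.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, data) {
  stopifnot(inherits(model, "fitted_model"))
  X <- encode_design(data, model$schema)
  p <- model$adapter$predict_fn(model$state, X)
  stopifnot(length(p) == nrow(X))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s trained on %d rows (%d cases)\n",
              x$adapter$label, cohort_size(x$train_cohort),
              sum(x$train_cohort$outcome)))
  invisible(x)
}

# --- concrete adapters -------------------------------------------------

adapter_logistic <- function() {
  model_adapter(
    "logistic",
    fit_fn = function(X, y, seed) {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                       family = stats::binomial()))
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      cf
    },
    predict_fn = function(state, X) {
      as.numeric(logistic(cbind(1, X) %*% state))
    },
    params = list(family = "binomial")
  )
}

adapter_random_forest <- function(num_trees = 500L, max_depth = 5L) {
  model_adapter(
    "random_forest",
    fit_fn = function(X, y, seed) {
      ranger::ranger(x = as.data.frame(X, check.names = FALSE),
                     y = factor(y, levels = c(0L, 1L)),
                     probability = TRUE, num.trees = num_trees,
                     max.depth = max_depth, seed = seed, num.threads = 1L)
    },
    predict_fn = function(state, X) {
      stats::predict(state, data = as.data.frame(X, check.names = FALSE),
                     num.threads = 1L)$predictions[, "1"]
    },
    params = list(num.trees = num_trees, max.depth = max_depth)
  )
}

adapter_xgboost <- function(nrounds = 100L, max_depth = 5L, eta = 0.3) {
  model_adapter(
    "xgboost",
    fit_fn = function(X, y, seed) {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = eta, nthread = 1L, seed = seed),
        data = xgboost::xgb.DMatrix(X, label = y), nrounds = nrounds)
    },
    predict_fn = function(state, X) {
      stats::predict(state, xgboost::xgb.DMatrix(X))
    },
    params = list(nrounds = nrounds, max_depth = max_depth, eta = eta)
  )
}

adapter_mlp <- function(size = 8L, decay = 0, maxit = 100L) {
  model_adapter(
    "mlp",
    fit_fn = function(X, y, seed) {
      # standardize inputs: single-hidden-layer nets are scale sensitive
      mu <- colMeans(X)
      sd <- apply(X, 2, stats::sd)
      sd[sd < 1e-12] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
      net <- withr::with_seed(seed,
        nnet::nnet(Xs, y, size = size, decay = decay, maxit = maxit,
                   entropy = TRUE, trace = FALSE))
      list(net = net, mu = mu, sd = sd)
    },
    predict_fn = function(state, X) {
      Xs <- sweep(sweep(X, 2, state$mu), 2, state$sd, "/")
      as.numeric(stats::predict(state$net, Xs))
    },
    params = list(size = size, decay = decay, maxit = maxit,
                  standardized_inputs = TRUE)
  )
}

#' Registry of available model adapters
#'
#' Exposes gradient-boosted trees and a random forest (both with
#' `max_depth = 5`, other training parameters at library defaults), a
#' single-hidden-layer perceptron, and a plain logistic model. The logistic
#' adapter is the test workhorse: its fitted probabilities have closed-form
#' structure against which the explainers can be checked.
#'
#' @param names optional character vector to look up; errors listing the
#'   available names if any is unknown.
#' @return named list of [model_adapter()] objects.
#' @export
model_adapter_registry <- function(names = NULL) {
  reg <- list(
    logistic = adapter_logistic(),
    random_forest = adapter_random_forest(),
    xgboost = adapter_xgboost(),
    mlp = adapter_mlp()
  )
  if (is.null(names)) return(reg)
  unknown <- setdiff(names, base::names(reg))
  if (length(unknown))
    stop("unknown model adapter(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(base::names(reg), collapse = ", "))
  reg[names]
}
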