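#' @title Feature-attribution explanations
#' @description Constructors and shared helpers for per-instance
#'   explanations. An `explanation` holds one named attribution per cohort
#'   feature (LIME surrogate coefficients or Shapley values), the base value
#'   (LIME intercept, or the expected model output over the background for
#'   Shapley), and the model's prediction for the explained instance.
#' @param instance_id identifier of the explained instance.
#' @param method `"lime"` or `"shapley"`.
#' @param attribution named numeric vector, one entry per feature.
#' @param base_value intercept / expected output.
#' @param prediction model output at the instance.
#' @return an object of class `explanation`.
#' @export
new_explanation <- function(instance_id, method = c("lime", "shapley"),
                            attribution, base_value, prediction) {
  method <- match.arg(method)
  stopifnot(is.numeric(attribution), !is.null(names(attribution)),
            all(nzchar(names(attribution))))
  structure(list(instance_id = instance_id, method = method,
                 attribution = attribution, base_value = base_value,
                 prediction = prediction),
            class = "explanation")
}

#' @export
print.explanation <- function(x, ...) {
  cat(sprintf("<explanation> %s for instance %s (f(x) = %.4f, base = %.4f)\n",
              x$method, format(x$instance_id), x$prediction, x$base_value))
  ord <- order(-abs(x$attribution))
  print(round(x$attribution[ord], 4))
  invisible(x)
}

# Explainers accept a fitted_model or any function mapping a conforming
# feature data.frame to probabilities; tests use hand-built closures.
as_predictor <- function(model) {
  if (inherits(model, "fitted_model")) {
    function(data) predict_prob(model, data)
  } else if (is.function(model)) {
    model
  } else stop("model must be a fitted_model or a prediction function")
}

#' Default explanation background for a fitted model
#'
#' The model's own training cohort, capped by a seeded random subsample so
#' explanation cost stays bounded.
#'
#' @param model a `fitted_model`.
#' @param cap maximum number of background rows.
#' @param seed seed for the subsample.
#' @return a `cohort` to use as Shapley/LIME/PDP background.
#' @export
default_background <- function(model, cap = 200L, seed = 1L) {
  stopifnot(inherits(model, "fitted_model"))
  bg <- model$train_cohort
  if (cohort_size(bg) > cap) {
    idx <- withr::with_seed(seed, sample(cohort_size(bg), cap))
    bg <- cohort_rows(bg, sort(idx), source = "background")
  }
  bg
}

#' LIME explainer configuration
#'
#' @param n_perturbations number of perturbed samples `Z` drawn around the
#'   instance (must exceed the feature count + 1).
#' @param kernel_width bandwidth of the exponential proximity kernel
#'   `exp(-D^2 / width^2)` on Euclidean distance in the interpretable
#'   representation; `NULL` means the conventional `0.75 * sqrt(d)` where
#'   `d` is the representation dimension.
#' @param ridge_penalty L2 penalty on the non-intercept surrogate
#'   coefficients; a small positive default stabilises the solve, 0 is
#'   allowed.
#' @param seed integer seed for the perturbation draw.
#' @return an object of class `lime_config`.
#' @export
lime_config <- function(n_perturbations = 1000L, kernel_width = NULL,
                        ridge_penalty = 1e-6, seed = 1L) {
  stopifnot(n_perturbations >= 3L, is.null(kernel_width) || kernel_width > 0,
            ridge_penalty >= 0)
  structure(list(n_perturbations = as.integer(n_perturbations),
                 kernel_width = kernel_width,
                 ridge_penalty = ridge_penalty, seed = as.integer(seed)),
            class = "lime_config")
}

# interpretable representation used by the LIME surrogate: continuous
# features standardized against the background; categorical/binary features
# mapped to a "same level as the instance" indicator
lime_representation <- function(data, instance, schema, center, scale) {
  rep_cols <- lapply(schema, function(s) {
    x <- data[[s$name]]
    if (s$kind == "continuous") {
      (as.numeric(x) - center[[s$name]]) / scale[[s$name]]
    } else {
      as.numeric(as.character(x) == as.character(instance[[s$name]][1L]))
    }
  })
  m <- do.call(cbind, rep_cols)
  colnames(m) <- vapply(schema, `[[`, character(1), "name")
  m
}

#' Explain one prediction with a local weighted linear surrogate (LIME)
#'
#' Draws perturbed samples around the instance, queries the black box on
#' each, and solves the proximity-weighted ridge regression in closed form
#' (weighted normal equations; the intercept is unpenalized). Continuous
#' features are perturbed with unit-variance Gaussian noise in standardized
#' coordinates; categorical and binary features are resampled from the
#' background marginals. The surrogate is fit on the interpretable
#' representation, so a categorical feature's attribution is the
#' coefficient of its "equals the instance's level" indicator.
#'
#' @param model a `fitted_model` or prediction function.
#' @param instance one-row feature data frame.
#' @param background background `cohort` (defines standardization and
#'   categorical marginals).
#' @param config a [lime_config()].
#' @param instance_id identifier carried into the explanation.
#' @return an `explanation` with `method = "lime"`.
#' @export
lime_explain <- function(model, instance, background,
                         config = lime_config(), instance_id = NA) {
  stopifnot(inherits(background, "cohort"), nrow(instance) == 1L)
  f <- as_predictor(model)
  schema <- background$schema
  p <- length(schema)
  if (config$n_perturbations < p + 2L)
    stop("n_perturbations must be at least p + 2")

  cont <- vapply(schema, function(s) s$kind == "continuous", logical(1))
  center <- lapply(schema, function(s)
    if (s$kind == "continuous") mean(as.numeric(background$data[[s$name]])) else NA)
  scale <- lapply(schema, function(s) {
    if (s$kind != "continuous") return(NA)
    sd <- stats::sd(as.numeric(background$data[[s$name]]))
    if (!is.finite(sd) || sd < 1e-12) 1 else sd
  })
  names(center) <- names(scale) <- vapply(schema, `[[`, character(1), "name")

  n <- config$n_perturbations
  Z <- withr::with_seed(config$seed, {
    cols <- lapply(schema, function(s) {
      x0 <- instance[[s$name]][1L]
      if (s$kind == "continuous") {
        z_std <- (as.numeric(x0) - center[[s$name]]) / scale[[s$name]] +
          stats::rnorm(n)
        center[[s$name]] + scale[[s$name]] * z_std
      } else {
        pool <- background$data[[s$name]]
        smp <- pool[sample.int(length(pool), n, replace = TRUE)]
        if (s$kind == "binary") as.integer(as.numeric(smp)) else
          factor(as.character(smp), levels = s$levels)
      }
    })
    names(cols) <- vapply(schema, `[[`, character(1), "name")
    as.data.frame(cols, optional = TRUE, check.names = FALSE)
  })
  # row 1 is the instance itself (zero distance, maximal weight)
  Z[1L, ] <- instance[1L, names(Z)]

  y <- f(Z)
  R <- lime_representation(Z, instance, schema, center, scale)
  r0 <- R[1L, ]
  d2 <- rowSums(sweep(R, 2, r0)^2)
  width <- config$kernel_width %||% (0.75 * sqrt(p))
  w <- exp(-d2 / width^2)

  X <- cbind(`(Intercept)` = 1, R)
  XtW <- t(X * w)
  A <- XtW %*% X
  pen <- diag(c(0, rep(config$ridge_penalty, p)))
  b <- XtW %*% y
  beta <- tryCatch(solve(A + pen, b), error = function(e) {
    if (config$ridge_penalty == 0)
      stop("weighted design is singular with zero ridge penalty; ",
           "set ridge_penalty > 0", call. = FALSE)
    stop(e)
  })
  beta <- drop(beta)
  attribution <- beta[-1L]
  names(attribution) <- colnames(R)
  new_explanation(instance_id, "lime", attribution,
                  base_value = beta[[1L]], prediction = y[1L])
}

#' Coalition value function (marginal-expectation estimator)
#'
#' Expected model output when the features in `coalition` are fixed to the
#' instance's values and the remaining features keep their background
#' values, averaged over the background rows. This is the interventional
#' (marginal) estimator of the coalition value: absent features are drawn
#' from the background marginal rather than a conditional distribution.
#'
#' @param model a `fitted_model` or prediction function.
#' @param instance one-row feature data frame.
#' @param coalition character vector of feature names (may be empty).
#' @param background background `cohort`.
#' @return scalar expected output.
#' @export
value_function <- function(model, instance, coalition, background) {
  stopifnot(inherits(background, "cohort"))
  if (cohort_size(background) == 0L) stop("background must be nonempty")
  unknown <- setdiff(coalition, names(background$data))
  if (length(unknown))
    stop("coalition names not in the feature set: ",
         paste(unknown, collapse = ", "))
  f <- as_predictor(model)
  d <- background$data
  for (nm in coalition) d[[nm]] <- rep(instance[[nm]][1L], nrow(d))
  mean(f(d))
}

# batched coalition-value evaluator: returns function(masks) -> one value
# per mask row. For a fitted_model the substitution happens on the encoded
# design matrix (one-hot substitution commutes with encoding), which avoids
# rebuilding data frames in the permutation loop; arbitrary prediction
# functions fall back to the data-frame path.
make_value_fn <- function(model, instance, background, feat_names) {
  nbg <- nrow(background$data)
  if (inherits(model, "fitted_model")) {
    Xbg <- encode_design(background$data, background$schema)
    xin <- encode_design(instance, background$schema)
    col_map <- lapply(background$schema, function(s) {
      if (s$kind == "categorical") paste0(s$name, "=", s$levels[-1]) else s$name
    })
    col_idx <- lapply(col_map, function(cn) match(cn, colnames(Xbg)))
    function(masks) {
      big <- Xbg[rep.int(seq_len(nbg), nrow(masks)), , drop = FALSE]
      for (i in seq_len(nrow(masks))) {
        cols <- unlist(col_idx[masks[i, ]], use.names = FALSE)
        if (length(cols))
          big[((i - 1L) * nbg + 1L):(i * nbg), cols] <-
            matrix(xin[1L, cols], nbg, length(cols), byrow = TRUE)
      }
      p <- pmin(pmax(as.numeric(model$adapter$predict_fn(model$state, big)), 0), 1)
      colMeans(matrix(p, nrow = nbg))
    }
  } else {
    f <- as_predictor(model)
    function(masks) {
      blocks <- lapply(seq_len(nrow(masks)), function(i) {
        d <- background$data
        for (j in which(masks[i, ]))
          d[[feat_names[j]]] <- rep(instance[[feat_names[j]]][1L], nbg)
        d
      })
      preds <- f(do.call(rbind, blocks))
      colMeans(matrix(preds, nrow = nbg))
    }
  }
}

#' Exact Shapley values by coalition enumeration
#'
#' Evaluates the marginal-expectation value function on all `2^p` coalitions
#' (each once, batched into model calls) and combines marginal contributions
#' with the Shapley factorial weights `|S|! (p - |S| - 1)! / p!`. The
#' resulting attributions satisfy efficiency: they sum to
#' `f(x) - E_background[f(X)]` up to floating-point error.
#'
#' @param model a `fitted_model` or prediction function.
#' @param instance one-row feature data frame.
#' @param background background `cohort`.
#' @param exact_cap refuse instances with more features than this (default
#'   12; the cost is `2^p` coalition evaluations).
#' @param instance_id identifier carried into the explanation.
#' @return an `explanation` with `method = "shapley"`.
#' @export
shapley_exact <- function(model, instance, background, exact_cap = 12L,
                          instance_id = NA) {
  stopifnot(inherits(background, "cohort"), nrow(instance) == 1L)
  feat_names <- vapply(background$schema, `[[`, character(1), "name")
  p <- length(feat_names)
  if (p > exact_cap)
    stop("p = ", p, " exceeds the exact-mode cap (", exact_cap,
         "); use shapley_sampled()")
  n_coal <- 2L^p
  # coalition masks from bit patterns, value of each computed exactly once
  masks <- matrix(FALSE, n_coal, p)
  for (j in seq_len(p))
    masks[, j] <- bitwAnd(seq_len(n_coal) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  v <- make_value_fn(model, instance, background, feat_names)(masks)
  sizes <- rowSums(masks)
  lw <- lfactorial(seq(0, p - 1)) + lfactorial(p - seq(0, p - 1) - 1) - lfactorial(p)
  phi <- numeric(p)
  bit <- bitwShiftL(1L, seq_len(p) - 1L)
  ids <- seq_len(n_coal) - 1L
  for (i in seq_len(p)) {
    without <- bitwAnd(ids, bit[i]) == 0L
    with_i <- which(without) + bit[i] # index of S ∪ {i} (1-based offset holds)
    s <- sizes[without]
    phi[i] <- sum(exp(lw[s + 1L]) * (v[with_i] - v[which(without)]))
  }
  names(phi) <- feat_names
  new_explanation(instance_id, "shapley", phi,
                  base_value = v[1L], prediction = v[n_coal])
}

#' Shapley values by permutation sampling
#'
#' Monte-Carlo estimator of the exact Shapley attribution: marginal
#' contributions are averaged over uniformly sampled feature orderings. The
#' telescoping construction makes the estimate satisfy efficiency exactly
#' for every permutation. With `enumerate = TRUE` all `p!` orderings are
#' used instead of sampling, which reproduces the exact values.
#'
#' @param model a `fitted_model` or prediction function.
#' @param instance one-row feature data frame.
#' @param background background `cohort`.
#' @param n_permutations number of sampled orderings.
#' @param seed integer seed.
#' @param enumerate use all `p!` orderings instead of sampling.
#' @param instance_id identifier carried into the explanation.
#' @return an `explanation` with `method = "shapley"`.
#' @export
shapley_sampled <- function(model, instance, background,
                            n_permutations = 200L, seed = 1L,
                            enumerate = FALSE, instance_id = NA) {
  stopifnot(inherits(background, "cohort"), nrow(instance) == 1L,
            n_permutations >= 1L)
  feat_names <- vapply(background$schema, `[[`, character(1), "name")
  p <- length(feat_names)
  value_fn <- make_value_fn(model, instance, background, feat_names)
  perms <- if (enumerate) {
    all_permutations(p)
  } else {
    withr::with_seed(seed,
      lapply(seq_len(n_permutations), function(i) sample.int(p)))
  }
  phi <- numeric(p)
  base_v <- NA_real_
  full_v <- NA_real_
  for (perm in perms) {
    # masks for the p+1 prefixes of this ordering, one batched model call
    masks <- matrix(FALSE, p + 1L, p)
    for (step in seq_len(p)) masks[step + 1L, perm[seq_len(step)]] <- TRUE
    v <- value_fn(masks)
    phi[perm] <- phi[perm] + diff(v)
    base_v <- v[1L]
    full_v <- v[p + 1L]
  }
  phi <- phi / length(perms)
  names(phi) <- feat_names
  new_explanation(instance_id, "shapley", phi,
                  base_value = base_v, prediction = full_v)
}

all_permutations <- function(p) {
  if (p == 1L) return(list(1L))
  sub <- all_permutations(p - 1L)
  out <- list()
  for (s in sub) for (pos in seq_len(p)) out[[length(out) + 1L]] <- append(s, p, after = pos - 1L)
  out
}

#' Global feature importance from per-instance attributions
#'
#' The per-feature mean of absolute attributions across a set of
#' explanations — the standard mean-|SHAP| global importance score.
#'
#' @param explanations nonempty list of `explanation` objects sharing a
#'   feature name set.
#' @return named nonnegative numeric vector.
#' @export
global_importance <- function(explanations) {
  if (!length(explanations)) stop("explanations list is empty")
  nms <- names(explanations[[1L]]$attribution)
  mats <- vapply(explanations, function(e) {
    if (!setequal(names(e$attribution), nms))
      stop("explanations do not share a feature name set")
    abs(e$attribution[nms])
  }, numeric(length(nms)))
  if (is.null(dim(mats))) return(stats::setNames(abs(mats), nms))
  rowMeans(mats)
}

#' Partial dependence of the model on a continuous feature
#'
#' For each grid value, the feature is overwritten in every background row
#' and the model output averaged — the empirical marginalization of the
#' model over the remaining features.
#'
#' @param model a `fitted_model` or prediction function.
#' @param background background `cohort`.
#' @param feature continuous feature name.
#' @param grid strictly increasing numeric grid.
#' @return an object of class `pdp_curve`.
#' @export
pdp_continuous <- function(model, background, feature, grid) {
  stopifnot(inherits(background, "cohort"), length(grid) >= 1L)
  s <- background$schema[[feature]]
  if (is.null(s)) stop("unknown feature '", feature, "'")
  if (s$kind != "continuous") stop("'", feature, "' is not continuous")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  f <- as_predictor(model)
  mp <- vapply(grid, function(g) {
    d <- background$data
    d[[feature]] <- rep(g, nrow(d))
    mean(f(d))
  }, numeric(1))
  structure(list(feature = feature, grid = grid, mean_prediction = mp,
                 n_background = cohort_size(background)),
            class = "pdp_curve")
}

#' Partial dependence of the model on a categorical feature
#'
#' One averaged prediction per declared level, in the declared level order,
#' obtained by forcing every background row to that category.
#'
#' @param model a `fitted_model` or prediction function.
#' @param background background `cohort`.
#' @param feature categorical (or binary) feature name.
#' @return an object of class `pdp_curve` whose grid is the level list.
#' @export
pdp_categorical <- function(model, background, feature) {
  stopifnot(inherits(background, "cohort"))
  s <- background$schema[[feature]]
  if (is.null(s)) stop("unknown feature '", feature, "'")
  levels <- if (s$kind == "categorical") s$levels else c(0L, 1L)
  if (!length(levels)) stop("feature '", feature, "' declares no levels")
  f <- as_predictor(model)
  mp <- unname(vapply(levels, function(lv) {
    d <- background$data
    d[[feature]] <- if (s$kind == "categorical")
      factor(rep(lv, nrow(d)), levels = s$levels) else rep(as.integer(lv), nrow(d))
    mean(f(d))
  }, numeric(1)))
  structure(list(feature = feature, grid = levels, mean_prediction = mp,
                 n_background = cohort_size(background)),
            class = "pdp_curve")
}

#' @export
print.pdp_curve <- function(x, ...) {
  cat(sprintf("<pdp_curve> %s over %d grid points (background n = %d)\n",
              x$feature, length(x$grid), x$n_background))
  print(data.frame(grid = x$grid, mean_prediction = round(x$mean_prediction, 4)))
  invisible(x)
}

#' Serialize explanations to a tidy data frame
#'
#' @param explanations list of `explanation` objects.
#' @return data frame with columns instance_id, method, feature,
#'   attribution, base_value, prediction.
#' @export
explanations_to_df <- function(explanations) {
  do.call(rbind, lapply(explanations, function(e) {
    data.frame(instance_id = e$instance_id, method = e$method,
               feature = names(e$attribution),
               attribution = as.numeric(e$attribution),
               base_value = e$base_value, prediction = e$prediction,
               row.names = NULL)
  }))
}

#' Serialize a PDP curve to a tidy data frame
#' @param curve a `pdp_curve`.
#' @return data frame with columns feature, grid, mean_prediction.
#' @export
pdp_to_df <- function(curve) {
  data.frame(feature = curve$feature, grid = as.character(curve$grid),
             mean_prediction = curve$mean_prediction, row.names = NULL)
}
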