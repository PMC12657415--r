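make_bg <- function(p = 3, n = 8, seed = 2, effects = rep(0, p)) {
  generate_cohort(numeric_spec(p = p, n = n, effects = effects), seed = seed)
}

test_that("value_function marginalizes absent features over the background", {
  bg <- make_bg(p = 2, n = 2, seed = 1)
  f <- function(d) plogis(0.7 * d$x1 - 1.3 * d$x2)
  x <- data.frame(x1 = 0.4, x2 = -1.1)

  # full coalition: nothing marginalized
  expect_equal(value_function(f, x, c("x1", "x2"), bg), f(x))
  # empty coalition: mean model output over the background
  expect_equal(value_function(f, x, character(0), bg), mean(f(bg$data)))
  # singleton coalition with 2 background rows: hand-enumerable average
  by_hand <- mean(c(f(data.frame(x1 = 0.4, x2 = bg$data$x2[1])),
                    f(data.frame(x1 = 0.4, x2 = bg$data$x2[2]))))
  expect_equal(value_function(f, x, "x1", bg), by_hand)

  expect_error(value_function(f, x, "nope", bg), "nope")
})

test_that("exact Shapley values satisfy the dummy, linearity and efficiency properties", {
  bg <- make_bg(p = 3, n = 10)
  x <- data.frame(x1 = 1.2, x2 = -0.3, x3 = 0.8)

  # constant model: every attribution is zero
  e0 <- shapley_exact(function(d) rep(0.42, nrow(d)), x, bg)
  expect_equal(unname(e0$attribution), rep(0, 3), tolerance = 1e-12)

  # linear model with the marginal value function: phi_i = beta_i (x_i - mean)
  beta <- c(x1 = 0.5, x2 = -1.1, x3 = 0.25)
  f_lin <- function(d) 0.1 + 0.5 * d$x1 - 1.1 * d$x2 + 0.25 * d$x3
  e_lin <- shapley_exact(f_lin, x, bg)
  expected <- beta * (unlist(x) - colMeans(bg$data))
  expect_equal(e_lin$attribution, expected, tolerance = 1e-10)

  # efficiency: sum phi = f(x) - E_bg[f(X)]
  f_nl <- function(d) plogis(d$x1 * d$x2 - 0.5 * d$x3^2)
  e_nl <- shapley_exact(f_nl, x, bg)
  expect_equal(sum(e_nl$attribution), f_nl(x) - mean(f_nl(bg$data)),
               tolerance = 1e-8)
})

test_that("exact Shapley equals the permutation-enumeration oracle", {
  for (seed in 1:3) {
    bg <- make_bg(p = 3, n = 6, seed = seed)
    x <- bg$data[1, , drop = FALSE]
    f <- function(d) plogis(0.8 * d$x1 - d$x2 + 0.4 * d$x1 * d$x3)
    e <- shapley_exact(f, x, bg)
    oracle <- shapley_permutation_oracle(f, x, bg)
    expect_equal(e$attribution, oracle, tolerance = 1e-10)
  }
  # and with a mixed-type schema (factor substitution path)
  bg_mix <- generate_cohort(tiny_spec(n = 6), seed = 4)
  x_mix <- bg_mix$data[2, , drop = FALSE]
  f_mix <- function(d) plogis(d$x1 - 0.5 * d$x2 + (d$smk == "c"))
  e_mix <- shapley_exact(f_mix, x_mix, bg_mix)
  expect_equal(e_mix$attribution,
               shapley_permutation_oracle(f_mix, x_mix, bg_mix),
               tolerance = 1e-10)
})

test_that("symmetric features receive equal Shapley values", {
  bg <- make_bg(p = 2, n = 12, seed = 7)
  bg$data$x2 <- bg$data$x1 # identical values and identical model role
  f <- function(d) plogis(d$x1 + d$x2)
  x <- data.frame(x1 = 0.9, x2 = 0.9)
  e <- shapley_exact(f, x, bg)
  expect_equal(e$attribution[["x1"]], e$attribution[["x2"]], tolerance = 1e-10)
})

test_that("the exact-mode cap redirects to sampling", {
  spec <- numeric_spec(p = 13, n = 5)
  bg <- generate_cohort(spec, seed = 1)
  x <- bg$data[1, , drop = FALSE]
  expect_error(shapley_exact(function(d) rep(0.5, nrow(d)), x, bg),
               "shapley_sampled")
})

test_that("sampled Shapley is exact under full enumeration and converges", {
  bg <- make_bg(p = 4, n = 6, seed = 9)
  x <- bg$data[3, , drop = FALSE]
  f <- function(d) plogis(d$x1 * d$x2 - d$x3 + 0.5 * d$x4)

  exact <- shapley_exact(f, x, bg)
  enum <- shapley_sampled(f, x, bg, enumerate = TRUE)
  expect_equal(enum$attribution, exact$attribution, tolerance = 1e-10)

  # constant model: zero for any seed
  e0 <- shapley_sampled(function(d) rep(0.3, nrow(d)), x, bg,
                        n_permutations = 5, seed = 11)
  expect_equal(unname(e0$attribution), rep(0, 4), tolerance = 1e-12)

  # per-permutation telescoping keeps efficiency exact even when sampled
  e_s <- shapley_sampled(f, x, bg, n_permutations = 7, seed = 3)
  expect_equal(sum(e_s$attribution), f(x) - mean(f(bg$data)),
               tolerance = 1e-10)

  # Monte-Carlo error shrinks roughly like 1/sqrt(n_permutations)
  err_at <- function(n_perm) {
    errs <- vapply(1:12, function(s) {
      est <- shapley_sampled(f, x, bg, n_permutations = n_perm, seed = s)
      max(abs(est$attribution - exact$attribution))
    }, numeric(1))
    mean(errs)
  }
  e10 <- err_at(10); e100 <- err_at(100)
  expect_lt(e100, e10) # strictly shrinking on average
  expect_lt(e100, e10 / sqrt(10) * 3) # within 3x of the theoretical rate
})

test_that("LIME recovers local linear structure", {
  bg <- make_bg(p = 3, n = 50, seed = 21)
  x <- data.frame(x1 = 0.2, x2 = -0.4, x3 = 1.0)
  mu <- colMeans(bg$data); sd <- apply(bg$data, 2, sd)

  # constant black box: zero coefficients, intercept = the constant
  e0 <- lime_explain(function(d) rep(0.37, nrow(d)), x, bg,
                     lime_config(300, seed = 1))
  expect_equal(unname(e0$attribution), rep(0, 3), tolerance = 1e-8)
  expect_equal(e0$base_value, 0.37, tolerance = 1e-8)

  # exactly-linear target in standardized coordinates, zero penalty:
  # weighted least squares recovers the coefficients for any kernel
  f_lin <- function(d) {
    0.3 + 0.5 * (d$x1 - mu[1]) / sd[1] - 0.2 * (d$x2 - mu[2]) / sd[2] +
      0.05 * (d$x3 - mu[3]) / sd[3]
  }
  for (width in c(0.4, 1.5)) {
    e <- lime_explain(f_lin, x, bg,
                      lime_config(400, kernel_width = width,
                                  ridge_penalty = 0, seed = 2))
    expect_equal(unname(e$attribution), c(0.5, -0.2, 0.05), tolerance = 1e-6)
    expect_equal(e$base_value, 0.3, tolerance = 1e-6)
  }

  # linearity in the target: coefficients of f1 + f2 are the sums, at
  # identical perturbations and weights (same config seed)
  f1 <- function(d) 0.1 + 0.3 * d$x1
  f2 <- function(d) 0.2 - 0.4 * d$x2 + 0.1 * d$x3
  cfg <- lime_config(300, ridge_penalty = 0, seed = 5)
  e1 <- lime_explain(f1, x, bg, cfg)
  e2 <- lime_explain(f2, x, bg, cfg)
  e12 <- lime_explain(function(d) f1(d) + f2(d), x, bg, cfg)
  expect_equal(e12$attribution, e1$attribution + e2$attribution,
               tolerance = 1e-8)
  expect_equal(e12$base_value, e1$base_value + e2$base_value,
               tolerance = 1e-8)
})

test_that("LIME is deterministic under its seed and handles categoricals", {
  bg <- generate_cohort(tiny_spec(n = 60), seed = 6)
  x <- bg$data[1, , drop = FALSE]
  f <- function(d) plogis(d$x1 + (d$smk == as.character(x$smk)))
  cfg <- lime_config(250, seed = 8)
  e1 <- lime_explain(f, x, bg, cfg)
  e2 <- lime_explain(f, x, bg, cfg)
  expect_identical(e1$attribution, e2$attribution)
  # the instance-level indicator for the active categorical is positive
  expect_gt(e1$attribution[["smk"]], 0)
})

test_that("global importance is the mean of absolute attributions", {
  feats <- c("a", "b")
  e1 <- new_explanation(1, "shapley", c(a = 1, b = -1), 0, 0.5)
  e2 <- new_explanation(2, "shapley", c(a = 3, b = 1), 0, 0.5)
  expect_equal(global_importance(list(e1, e2)), c(a = 2, b = 1))
  expect_equal(global_importance(list(e2, e1)), c(a = 2, b = 1))
  z <- new_explanation(3, "shapley", c(a = 0, b = 0), 0, 0.5)
  expect_equal(global_importance(list(z, z)), c(a = 0, b = 0))
  expect_error(global_importance(list()), "empty")
})

test_that("partial dependence marginalizes correctly", {
  bg <- make_bg(p = 2, n = 20, seed = 31)
  grid <- seq(-2, 2, length.out = 5)

  # model ignoring the feature: constant curve at the mean prediction
  f_ign <- function(d) plogis(0.9 * d$x2)
  curve <- pdp_continuous(f_ign, bg, "x1", grid)
  expect_equal(curve$mean_prediction, rep(mean(f_ign(bg$data)), 5),
               tolerance = 1e-12)

  # additive model: grid differences equal h differences exactly
  h <- function(v) 0.1 * v^2
  f_add <- function(d) h(d$x1) + 0.05 * d$x2
  curve2 <- pdp_continuous(f_add, bg, "x1", grid)
  expect_equal(diff(curve2$mean_prediction), diff(h(grid)), tolerance = 1e-12)

  # single-row background: the curve is f along the grid for that row
  bg1 <- generate_cohort(numeric_spec(p = 2, n = 2), seed = 1)
  bg1$data <- bg1$data[1, , drop = FALSE]
  bg1$outcome <- bg1$outcome[1]
  bg1$row_id <- 1L
  f <- function(d) plogis(d$x1 - 0.3 * d$x2)
  curve3 <- pdp_continuous(f, bg1, "x1", grid)
  expect_equal(curve3$mean_prediction,
               plogis(grid - 0.3 * bg1$data$x2[1]), tolerance = 1e-12)

  expect_error(pdp_continuous(f, bg, "nope", grid), "unknown feature")
  expect_error(pdp_continuous(f, bg, "x1", c(1, 0)), "strictly increasing")
})

test_that("categorical partial dependence follows the declared level order", {
  bg <- generate_cohort(tiny_spec(n = 40), seed = 12)

  f_ign <- function(d) plogis(d$x1)
  curve <- pdp_categorical(f_ign, bg, "smk")
  expect_equal(curve$grid, c("a", "b", "c"))
  expect_equal(diff(range(curve$mean_prediction)), 0, tolerance = 1e-12)

  # indicator model scaled by c: the profiled level stands out exactly
  f_ind <- function(d) 0.7 * (d$smk == "b")
  curve2 <- pdp_categorical(f_ind, bg, "smk")
  expect_equal(curve2$mean_prediction, c(0, 0.7, 0), tolerance = 1e-12)

  # the default smoking feature yields nine levels
  lung_bg <- generate_cohort(lung_cohort_spec(n = 30, target_prevalence = 0.3),
                             seed = 2)
  curve3 <- pdp_categorical(function(d) rep(0.5, nrow(d)), lung_bg,
                            "smoking_status")
  expect_length(curve3$grid, 9L)
})

test_that("explanations serialize to a tidy frame", {
  e1 <- new_explanation(10, "lime", c(a = 1, b = 2), 0.1, 0.9)
  df <- explanations_to_df(list(e1))
  expect_equal(names(df), c("instance_id", "method", "feature", "attribution",
                            "base_value", "prediction"))
  expect_equal(nrow(df), 2L)
})

test_that("matrix-level and data-frame coalition paths agree for fitted models", {
  co <- generate_cohort(tiny_spec(n = 120, intercept = 0), seed = 14)
  fit <- fit_model(model_adapter_registry("logistic")$logistic, co)
  bg <- default_background(fit, cap = 20, seed = 2)
  x <- co$data[5, , drop = FALSE]
  fast <- shapley_exact(fit, x, bg)
  slow <- shapley_exact(function(d) predict_prob(fit, d), x, bg)
  expect_equal(fast$attribution, slow$attribution, tolerance = 1e-12)
  fast_s <- shapley_sampled(fit, x, bg, n_permutations = 6, seed = 3)
  slow_s <- shapley_sampled(function(d) predict_prob(fit, d), x, bg,
                            n_permutations = 6, seed = 3)
  expect_equal(fast_s$attribution, slow_s$attribution, tolerance = 1e-12)
})
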