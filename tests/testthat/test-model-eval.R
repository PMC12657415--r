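test_that("roc_auc matches hand counts and the pair-enumeration oracle", {
  expect_equal(roc_auc(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)

  withr::with_seed(41, {
    for (i in 1:25) {
      n <- sample(6:30, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), 2) # rounding forces ties
      expect_equal(roc_auc(scores, labels), auc_pair_oracle(scores, labels))
    }
  })
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both outcome classes")
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    scores <- runif(200)
    labels <- rbinom(200, 1, plogis(3 * scores - 1.5))
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("youden_threshold maximizes J with the lowest-threshold tie rule", {
  # perfectly separated scores: J = 1
  yt <- youden_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(yt$J, 1)

  # hand-enumerated case with a J tie: the lower threshold wins
  yt2 <- youden_threshold(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(yt2$J, 0.5)
  expect_equal(yt2$threshold, 0.4)
  expect_equal(yt2$sensitivity, 1)
  expect_equal(yt2$specificity, 0.5)

  expect_equal(youden_threshold(rep(0.3, 6), rep(c(0, 1), 3))$J, 0)

  # oracle equivalence over random score/label draws
  withr::with_seed(13, {
    for (i in 1:100) {
      n <- sample(8:40, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
      scores <- round(runif(n), 2)
      yt <- youden_threshold(scores, labels)
      expect_equal(yt$J, youden_oracle(scores, labels), tolerance = 1e-12)
      expect_true(yt$threshold %in% scores)
    }
  })
})

test_that("bootstrap_metric resamples within class and tracks the point estimate", {
  withr::with_seed(3, {
    scores <- runif(300)
    labels <- rbinom(300, 1, plogis(4 * scores - 2))
  })
  reps <- bootstrap_metric(scores, labels, "auc", n_boot = 100, seed = 5)
  expect_length(reps, 100L)
  expect_identical(reps, bootstrap_metric(scores, labels, "auc", 100, seed = 5))
  point <- roc_auc(scores, labels)
  expect_lt(abs(mean(reps) - point), 3 * sd(reps))

  # degenerate perfectly-separated input: every replicate is 1
  s2 <- c(rep(1, 20), rep(0, 20)); l2 <- c(rep(1, 20), rep(0, 20))
  expect_equal(bootstrap_metric(s2, l2, "auc", 10, seed = 1), rep(1, 10))

  expect_error(bootstrap_metric(scores, labels, "f1", 10, seed = 1),
               "unknown metric")
})

test_that("mann_whitney_u reproduces exact and limiting cases", {
  # complete separation of two size-3 samples: U = 0, exact p = 2/20
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)

  # identical samples: U = n_a n_b / 2 and p ~ 1
  r2 <- mann_whitney_u(1:10, 1:10)
  expect_equal(r2$statistic, 50)
  expect_gt(r2$p_value, 0.99)

  # two-sided p invariant under swapping the samples
  withr::with_seed(77, {
    for (i in 1:20) {
      a <- rnorm(sample(3:25, 1)); b <- rnorm(sample(3:25, 1), mean = 0.4)
      expect_equal(mann_whitney_u(a, b)$p_value,
                   mann_whitney_u(b, a)$p_value, tolerance = 1e-12)
    }
  })
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("mann_whitney_u agrees with the standard implementation where policies coincide", {
  withr::with_seed(19, {
    # exact regime: small tie-free samples
    for (i in 1:10) {
      a <- rnorm(8); b <- rnorm(9, 0.5)
      expect_equal(mann_whitney_u(a, b)$p_value,
                   wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
    }
    # large-sample regime with ties: corrected normal approximation
    a <- round(rnorm(80), 1); b <- round(rnorm(90, 0.2), 1)
    expect_equal(mann_whitney_u(a, b)$p_value,
                 wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  })
})

test_that("mann_whitney_u type-I error is calibrated at the 5% level", {
  n_rep <- 5000
  rejections <- withr::with_seed(2024, {
    sum(vapply(seq_len(n_rep), function(i) {
      a <- rnorm(30); b <- rnorm(30)
      mann_whitney_u(a, b)$p_value < 0.05
    }, logical(1)))
  })
  expect_lt(abs(rejections / n_rep - 0.05), 0.01)
})

test_that("wilcoxon_signed_rank handles exact, tied and degenerate cases", {
  # all-positive differences of size 3: exact two-sided p = 2/8
  r <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 0.25)

  # identical pairs: degenerate with p = 1
  r2 <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(r2$degenerate)
  expect_equal(r2$p_value, 1)

  # swapping the pair flips the signed statistic; the p-value is unchanged
  withr::with_seed(31, {
    for (i in 1:15) {
      n <- sample(5:40, 1)
      a <- rnorm(n); b <- rnorm(n, 0.3)
      ra <- wilcoxon_signed_rank(a, b); rb <- wilcoxon_signed_rank(b, a)
      expect_equal(ra$p_value, rb$p_value, tolerance = 1e-12)
    }
  })

  # exact path agrees with the standard implementation when zero-free
  withr::with_seed(53, {
    for (i in 1:10) {
      a <- rnorm(10); b <- rnorm(10)
      expect_equal(wilcoxon_signed_rank(a, b)$p_value,
                   wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("zero differences are ranked then dropped under the Pratt policy", {
  # bounded consistency values tie at zero often; Pratt keeps those pairs in
  # the ranking so they still depress the significance of the rest
  a <- c(1, 1, 1, 0.4, 0.3, 0.2, 0.1, 0.05, 0.5, 0.6, 0.7, 0.8, 0.9, 0.45)
  b <- rep(1, length(a))
  pratt <- wilcoxon_signed_rank(a, b)
  drop0 <- wilcoxon_signed_rank(a, b, zeros = "wilcoxon")
  expect_lt(pratt$p_value, 1)
  expect_false(isTRUE(all.equal(pratt$p_value, drop0$p_value)))
  # Pratt statistic counts no zero ranks in the positive sum (all d <= 0 here)
  expect_equal(pratt$statistic, 0)
})

test_that("performance_summary reports a coherent operating point", {
  withr::with_seed(61, {
    scores <- runif(200)
    labels <- rbinom(200, 1, plogis(5 * scores - 2.5))
  })
  ps <- performance_summary(scores, labels, "m", "balanced")
  expect_true(ps$auc >= 0 && ps$auc <= 1)
  expect_true(ps$sensitivity >= 0 && ps$sensitivity <= 1)
  expect_true(ps$specificity >= 0 && ps$specificity <= 1)
  expect_true(ps$youden_threshold >= min(scores) &&
                ps$youden_threshold <= max(scores))
  expect_equal(ps$J, ps$sensitivity + ps$specificity - 1)
})
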