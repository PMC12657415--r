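check_two_classes <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' Rank-based estimator: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counted one half
#' (equivalent to the Mann-Whitney statistic scaled by `n1 * n0`).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  r <- rank(scores)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Operating point maximizing Youden's J
#'
#' Scans the distinct observed scores as candidate thresholds under the
#' classification rule `score >= t -> positive` and maximizes
#' `J(t) = sensitivity(t) + specificity(t) - 1`. Ties on J are broken by
#' the lowest threshold, favouring sensitivity.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes present).
#' @return list with `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  cand <- sort(unique(scores))
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)[1L] # cand sorted ascending: lowest wins
  list(threshold = cand[best], J = J[best],
       sensitivity = sens[best], specificity = spec[best])
}

metric_value <- function(metric, scores, labels) {
  switch(metric,
    auc = roc_auc(scores, labels),
    sensitivity = youden_threshold(scores, labels)$sensitivity,
    specificity = youden_threshold(scores, labels)$specificity,
    stop("unknown metric '", metric,
         "'; available: auc, sensitivity, specificity")
  )
}

#' Bootstrap distribution of a test-set performance metric
#'
#' Resamples (score, label) pairs with replacement, stratified by class so
#' both classes stay present in every replicate, and recomputes the metric.
#' Sensitivity and specificity are recomputed at each replicate's own
#' Youden-optimal threshold.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param metric `"auc"`, `"sensitivity"` or `"specificity"`.
#' @param n_boot number of replicates (>= 2).
#' @param seed integer seed.
#' @return numeric vector of `n_boot` metric values.
#' @export
bootstrap_metric <- function(scores, labels, metric = "auc", n_boot = 100L,
                             seed = 1L) {
  labels <- check_two_classes(labels)
  stopifnot(n_boot >= 2L)
  metric_value(metric, scores, labels) # validates the metric name up front
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      metric_value(metric, scores[idx], labels[idx])
    }, numeric(1))
  })
}

new_test_result <- function(test, statistic, p_value, n,
                            degenerate = FALSE, note = NULL) {
  structure(list(test = test, statistic = statistic,
                 p_value = min(max(p_value, 0), 1), n = n,
                 alternative = "two.sided", degenerate = degenerate,
                 note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %g, p = %g (n = %s)%s\n",
              x$test, x$statistic, x$p_value, paste(x$n, collapse = "/"),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midrank sums. The p-value uses exact enumeration of
#' the null distribution when `n_a * n_b <= 400` and there are no ties,
#' otherwise the normal approximation with tie-corrected variance and a
#' 0.5 continuity correction.
#'
#' @param sample_a,sample_b numeric vectors (each nonempty).
#' @return a `test_result` whose statistic is U for `sample_a`.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("samples must be nonempty")
  na <- length(sample_a); nb <- length(sample_b)
  r <- rank(c(sample_a, sample_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(sample_a, sample_b))
  has_ties <- any(ties > 1)
  if (!has_ties && na * nb <= 400) {
    p <- 2 * min(stats::pwilcox(U, na, nb),
                 stats::pwilcox(U - 1, na, nb, lower.tail = FALSE))
  } else {
    N <- na + nb
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(new_test_result(
      "mann_whitney_u", U, 1, c(na, nb), degenerate = TRUE,
      note = "all observations tied"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    if (U == mu) z <- 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_test_result("mann_whitney_u", U, p, c(na, nb))
}

#' Wilcoxon signed-rank test for paired samples (two-sided)
#'
#' Differences `a - b` are ranked by absolute value with midranks; zero
#' differences are handled by the Pratt method by default (zeros take part
#' in the ranking, then drop out of the signed sums) or discarded first
#' (`zeros = "wilcoxon"`). The p-value is exact (signed-rank null
#' distribution) when there are at most 12 nonzero differences with no ties
#' and no zeros, otherwise a tie-corrected normal approximation with a 0.5
#' continuity correction. If every difference is zero the result is flagged
#' degenerate with `p = 1`.
#'
#' @param paired_a,paired_b equal-length numeric vectors (n >= 2).
#' @param zeros `"pratt"` (default) or `"wilcoxon"`.
#' @return a `test_result` whose statistic is the positive-rank sum.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 zeros = c("pratt", "wilcoxon")) {
  zeros <- match.arg(zeros)
  stopifnot(length(paired_a) == length(paired_b), length(paired_a) >= 2L)
  d <- paired_a - paired_b
  if (all(d == 0))
    return(new_test_result("wilcoxon_signed_rank", 0, 1, length(d),
                           degenerate = TRUE, note = "all differences zero"))
  if (zeros == "wilcoxon") d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  nonzero <- d != 0
  n_zero <- sum(!nonzero)
  w_pos <- sum(r[nonzero & d > 0])
  n_nonzero <- sum(nonzero)
  abs_ties <- table(abs(d[nonzero]))
  exact_ok <- n_zero == 0L && n_nonzero <= 12L && all(abs_ties == 1)
  if (exact_ok) {
    p <- 2 * min(stats::psignrank(w_pos, n_nonzero),
                 stats::psignrank(w_pos - 1, n_nonzero, lower.tail = FALSE))
  } else {
    # Pratt-adjusted moments: ranks 1..n_zero are consumed by the zeros
    mu <- (n * (n + 1) - n_zero * (n_zero + 1)) / 4
    sigma2 <- (n * (n + 1) * (2 * n + 1) -
                 n_zero * (n_zero + 1) * (2 * n_zero + 1)) / 24 -
      sum(abs_ties^3 - abs_ties) / 48
    if (sigma2 <= 0)
      return(new_test_result("wilcoxon_signed_rank", w_pos, 1, n,
                             degenerate = TRUE, note = "zero variance"))
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    if (w_pos == mu) z <- 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_test_result("wilcoxon_signed_rank", w_pos, p, length(paired_a))
}

#' Summarize a model's performance on a test set
#'
#' AUC plus the Youden-optimal operating point (threshold, sensitivity,
#' specificity) on a scored test set.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param model_label,condition labels carried into the summary.
#' @return an object of class `performance_summary` (also a plain list).
#' @export
performance_summary <- function(scores, labels, model_label = "",
                                condition = "") {
  yt <- youden_threshold(scores, labels)
  structure(list(model = model_label, condition = condition,
                 auc = roc_auc(scores, labels),
                 youden_threshold = yt$threshold, J = yt$J,
                 sensitivity = yt$sensitivity, specificity = yt$specificity,
                 n_test = length(labels)),
            class = "performance_summary")
}
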