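# small cohort specs and independent oracles used across the suite

tiny_spec <- function(n = 60, intercept = 0) {
  cohort_spec(
    list(
      feature_spec("x1", "continuous", location = 0, scale = 1, effect = 1),
      feature_spec("x2", "binary", rate = 0.4, effect = -0.5),
      feature_spec("smk", "categorical", levels = c("a", "b", "c"),
                   probs = c(0.5, 0.3, 0.2), effect = c(0, 0.3, 0.6))
    ),
    intercept = intercept, target_prevalence = 0.5, n = n
  )
}

numeric_spec <- function(p = 3, n = 40, effects = rep(0, p)) {
  feats <- lapply(seq_len(p), function(j)
    feature_spec(paste0("x", j), "continuous", location = 0, scale = 1,
                 effect = effects[j]))
  cohort_spec(feats, intercept = 0, target_prevalence = 0.5, n = n)
}

# a cohort with prescribed class counts and a single cheap feature; used by
# the subset-arithmetic tests where only row identity and outcome matter
counts_cohort <- function(n_case, n_control) {
  n <- n_case + n_control
  new_cohort_for_tests(
    data.frame(x = seq_len(n) / n),
    c(rep(1L, n_case), rep(0L, n_control))
  )
}

new_cohort_for_tests <- function(data, outcome) {
  spec <- cohort_spec(list(feature_spec("x", "continuous", effect = 0)),
                      intercept = 0, target_prevalence = 0.5,
                      n = nrow(data))
  co <- generate_cohort(spec, seed = 1)
  co$data <- data
  co$outcome <- as.integer(outcome)
  co$row_id <- seq_len(nrow(data))
  co$schema <- list(x = list(name = "x", kind = "continuous", levels = NULL))
  co
}

# --- independent oracles -----------------------------------------------

# Shapley values by averaging marginal contributions over ALL p! orderings,
# computed with repeated calls to value_function (never the exact-mode path)
shapley_permutation_oracle <- function(model, instance, background) {
  feats <- names(background$data)
  p <- length(feats)
  perms <- all_perms_oracle(p)
  phi <- numeric(p)
  for (perm in perms) {
    prev <- value_function(model, instance, character(0), background)
    for (step in seq_len(p)) {
      coal <- feats[perm[seq_len(step)]]
      cur <- value_function(model, instance, coal, background)
      phi[perm[step]] <- phi[perm[step]] + (cur - prev)
      prev <- cur
    }
  }
  stats::setNames(phi / length(perms), feats)
}

all_perms_oracle <- function(p) {
  if (p == 1) return(list(1L))
  out <- list()
  for (s in all_perms_oracle(p - 1)) {
    for (pos in seq_len(p)) out[[length(out) + 1]] <- append(s, p, after = pos - 1)
  }
  out
}

# set/position enumeration oracle for the two ranking metrics
ranking_metrics_oracle <- function(feats_a, feats_b) {
  u <- unique(c(feats_a, feats_b))
  inter <- 0; same_pos <- 0
  for (s in u) {
    ia <- match(s, feats_a)
    ib <- match(s, feats_b)
    if (!is.na(ia) && !is.na(ib)) {
      inter <- inter + 1
      if (ia == ib) same_pos <- same_pos + 1
    }
  }
  c(jaccard = inter / length(u), rank_agreement = same_pos / length(u))
}

# AUC by enumerating all positive/negative pairs
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (a in pos) for (b in neg) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# Youden J by brute-force scan over all distinct scores
youden_oracle <- function(scores, labels) {
  best <- -Inf
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    best <- max(best, sens + spec - 1)
  }
  best
}

random_explanation <- function(feats, id = 1, method = "shapley") {
  new_explanation(id, method,
                  stats::setNames(stats::rnorm(length(feats)), feats),
                  base_value = 0.5, prediction = 0.5)
}
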