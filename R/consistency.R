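#' Top-k feature ranking of an explanation
#'
#' Features are ranked by descending attribution magnitude (the same
#' criterion as mean-|SHAP| global importance); ties are broken by ascending
#' feature name so rankings are deterministic. With fewer than `k` nonzero
#' attributions, zero-attribution features still occupy ranks (in
#' alphabetical order) so the ranking keeps length `min(k, p)`; an
#' explanation whose attributions are all zero is flagged as degenerate.
#'
#' @param explanation an `explanation`.
#' @param k ranking depth (>= 1; default 10).
#' @param by `"abs"` (default) ranks by |attribution|; `"signed"` by the
#'   signed value, descending.
#' @return an object of class `top_k_ranking`.
#' @export
top_k <- function(explanation, k = 10L, by = c("abs", "signed")) {
  stopifnot(inherits(explanation, "explanation"), k >= 1L)
  by <- match.arg(by)
  a <- explanation$attribution
  score <- if (by == "abs") abs(a) else a
  ord <- order(-score, names(a), method = "radix")
  feats <- names(a)[ord][seq_len(min(k, length(a)))]
  structure(list(features = feats, k = as.integer(k),
                 source = explanation$instance_id,
                 method = explanation$method,
                 degenerate = all(a == 0)),
            class = "top_k_ranking")
}

as_ranking <- function(x, k) {
  if (inherits(x, "top_k_ranking")) return(x)
  stopifnot(is.character(x), !anyDuplicated(x))
  structure(list(features = x, k = as.integer(k), source = NA,
                 method = NA, degenerate = FALSE),
            class = "top_k_ranking")
}

check_same_k <- function(a, b) {
  if (a$k != b$k)
    stop("rankings were built with different k (", a$k, " vs ", b$k, ")")
}

#' Jaccard similarity of two top-k feature sets
#'
#' `|intersection| / |union|` of the two rankings' feature sets;
#' order-insensitive.
#'
#' @param r_a,r_b `top_k_ranking` objects built with the same `k`.
#' @return value in `[0, 1]`.
#' @export
jaccard_top_k <- function(r_a, r_b) {
  check_same_k(r_a, r_b)
  length(intersect(r_a$features, r_b$features)) /
    length(union(r_a$features, r_b$features))
}

#' Union-normalized Rank Agreement of two top-k rankings
#'
#' Counts the features that appear in both rankings *at the same rank
#' position* and divides by the size of the union of the two top-k sets
#' (rather than by k, so disagreement about which features rank at all is
#' penalized the same way as in the Jaccard index). Two five-feature
#' rankings `{a,b,c,d,e}` and `{a,f,g,d,e}` share a, d, e at positions
#' 1, 4, 5 and have a seven-feature union, giving 3/7.
#'
#' @param r_a,r_b `top_k_ranking` objects built with the same `k`.
#' @return value in `[0, 1]`, never larger than [jaccard_top_k()] of the
#'   same pair.
#' @export
rank_agreement <- function(r_a, r_b) {
  check_same_k(r_a, r_b)
  n <- min(length(r_a$features), length(r_b$features))
  same_pos <- sum(r_a$features[seq_len(n)] == r_b$features[seq_len(n)])
  same_pos / length(union(r_a$features, r_b$features))
}

#' Per-instance explanation consistency against a reference
#'
#' Pairs reference and test explanations by instance identifier and, per
#' instance, computes the top-k Jaccard similarity and Rank Agreement
#' between the two models' explanations of that same instance. Returns the
#' per-instance values with their mean and standard error
#' (`sd / sqrt(n)`) per metric.
#'
#' @param reference_explanations,test_explanations lists of `explanation`
#'   objects covering the same instance identifiers.
#' @param k ranking depth.
#' @param comparison label for the comparison (e.g. `"40% vs balanced"`).
#' @param class_label `"all"`, `"minority"` or `"majority"`.
#' @param by ranking criterion passed to [top_k()].
#' @return an object of class `consistency_result`.
#' @export
consistency_profile <- function(reference_explanations, test_explanations,
                                k = 10L, comparison = "", class_label = "all",
                                by = "abs") {
  ids_ref <- vapply(reference_explanations, function(e) as.character(e$instance_id),
                    character(1))
  ids_test <- vapply(test_explanations, function(e) as.character(e$instance_id),
                     character(1))
  orphans <- c(setdiff(ids_ref, ids_test), setdiff(ids_test, ids_ref))
  if (length(orphans))
    stop("instance identifiers do not align; orphans: ",
         paste(unique(orphans), collapse = ", "))
  if (length(ids_ref) < 2L) stop("need at least 2 paired instances")
  test_by_id <- stats::setNames(test_explanations, ids_test)
  rows <- lapply(seq_along(reference_explanations), function(i) {
    e_ref <- reference_explanations[[i]]
    e_test <- test_by_id[[ids_ref[i]]]
    r_ref <- top_k(e_ref, k, by = by)
    r_test <- top_k(e_test, k, by = by)
    data.frame(instance_id = ids_ref[i],
               jaccard = jaccard_top_k(r_ref, r_test),
               rank_agreement = rank_agreement(r_ref, r_test),
               degenerate = r_ref$degenerate || r_test$degenerate,
               row.names = NULL)
  })
  per_instance <- do.call(rbind, rows)
  n <- nrow(per_instance)
  summ <- data.frame(
    metric = c("jaccard", "rank_agreement"),
    mean = c(mean(per_instance$jaccard), mean(per_instance$rank_agreement)),
    se = c(stats::sd(per_instance$jaccard),
           stats::sd(per_instance$rank_agreement)) / sqrt(n),
    n = n
  )
  structure(list(per_instance = per_instance, summary = summ,
                 comparison = comparison, class_label = class_label,
                 k = as.integer(k)),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("<consistency_result> %s [%s], k = %d, n = %d\n",
              x$comparison, x$class_label, x$k, nrow(x$per_instance)))
  print(transform(x$summary, mean = round(mean, 4), se = round(se, 4)))
  invisible(x)
}

#' Class-wise explanation consistency
#'
#' Selects (with a seed) `n_per_class` explained instances per outcome class
#' and runs [consistency_profile()] separately for the minority (cases) and
#' majority (non-cases) classes.
#'
#' @param reference_explanations,test_explanations aligned explanation
#'   lists.
#' @param labels named 0/1 vector: outcome class per instance identifier.
#' @param k ranking depth.
#' @param n_per_class instances per class.
#' @param seed integer seed for the per-class selection.
#' @param comparison comparison label.
#' @return list with elements `minority` and `majority`, each a
#'   `consistency_result`.
#' @export
classwise_consistency <- function(reference_explanations, test_explanations,
                                  labels, k = 10L, n_per_class = 100L,
                                  seed = 1L, comparison = "") {
  ids <- vapply(reference_explanations, function(e) as.character(e$instance_id),
                character(1))
  if (is.null(names(labels))) stop("labels must be named by instance id")
  lab <- labels[ids]
  if (anyNA(lab)) stop("labels missing for some explained instances")
  if (length(unique(lab)) < 2L)
    stop("both outcome classes must be present among explained instances")
  picks <- withr::with_seed(seed, {
    lapply(c(minority = 1L, majority = 0L), function(cl) {
      pool <- which(lab == cl)
      if (length(pool) < n_per_class)
        stop(sprintf("class %d has %d explained instances; %d requested",
                     cl, length(pool), n_per_class))
      sort(sample(pool, n_per_class))
    })
  })
  lapply(stats::setNames(names(picks), names(picks)), function(cl_name) {
    idx <- picks[[cl_name]]
    consistency_profile(reference_explanations[idx], test_explanations[idx],
                        k = k, comparison = comparison,
                        class_label = cl_name)
  })
}

#' Serialize consistency results to tidy data frames
#'
#' @param results list of `consistency_result` objects.
#' @return list with `per_instance` and `summary` data frames (long format,
#'   one row per comparison/class/metric/instance or
#'   comparison/class/metric).
#' @export
consistency_to_df <- function(results) {
  per <- do.call(rbind, lapply(results, function(r) {
    cbind(comparison = r$comparison, class = r$class_label, k = r$k,
          r$per_instance)
  }))
  summ <- do.call(rbind, lapply(results, function(r) {
    cbind(comparison = r$comparison, class = r$class_label, k = r$k,
          r$summary)
  }))
  rownames(per) <- rownames(summ) <- NULL
  list(per_instance = per, summary = summ)
}
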