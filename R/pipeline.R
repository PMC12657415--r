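#' Experiment configuration for a class-imbalance explanation sweep
#'
#' Bundles every tunable of the end-to-end protocol: cohort source,
#' stratified split, imbalance subset construction, model roster, explainer
#' settings, consistency ranking depth, and statistics settings. All
#' stage-level seeds are derived deterministically from `seed` via
#' [derive_seed()].
#'
#' @param cohort_spec a [cohort_spec()] for a synthetic cohort, or `NULL`
#'   when `cohort_csv` is given.
#' @param cohort_csv path to a cohort CSV written by [write_cohort()].
#' @param test_fraction stratified test fraction.
#' @param proportions minority proportions of the imbalance subsets, each in
#'   (0, 0.5]; the balanced 0.5 reference is always included.
#' @param total_size rows per subset (even); `NULL` means twice the training
#'   minority pool (the largest balanced subset the pool supports).
#' @param models character vector of registry adapter names.
#' @param k ranking depth for the consistency metrics.
#' @param n_explain number of shared explained instances (even; drawn half
#'   per class from the balanced test sample).
#' @param n_per_class instances per class for the class-wise analysis;
#'   defaults to `n_explain / 2`.
#' @param lime a [lime_config()] (its seed field is overridden per
#'   instance with derived sub-seeds).
#' @param shapley_permutations permutation count for sampled Shapley values.
#' @param background_cap background subsample size for Shapley and LIME.
#' @param pdp_features features to profile under the balanced and the most
#'   imbalanced condition.
#' @param pdp_grid_size grid size for continuous PDP features.
#' @param n_boot bootstrap replicates for the performance comparison.
#' @param test_n_per_class upper cap on the per-class size of the balanced
#'   test sample; the realized size is the smaller of this and the minority
#'   test count (`NULL` means the full minority test count).
#' @param seed master seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(cohort_spec = NULL, cohort_csv = NULL,
                              test_fraction = 0.2,
                              proportions = c(0.4, 0.3, 0.2, 0.1, 0.05, 0.01),
                              total_size = NULL,
                              models = c("logistic", "xgboost"),
                              k = 10L, n_explain = 50L, n_per_class = NULL,
                              lime = lime_config(n_perturbations = 200L),
                              shapley_permutations = 20L,
                              background_cap = 100L,
                              pdp_features = NULL, pdp_grid_size = 9L,
                              n_boot = 100L, test_n_per_class = NULL,
                              seed = 1L) {
  if (is.null(cohort_spec) && is.null(cohort_csv))
    stop("provide either cohort_spec or cohort_csv")
  if (any(proportions <= 0 | proportions > 0.5))
    stop("proportions must lie in (0, 0.5]")
  stopifnot(k >= 1L, n_explain %% 2 == 0, n_explain >= 4L)
  structure(list(
    cohort_spec = cohort_spec, cohort_csv = cohort_csv,
    test_fraction = test_fraction,
    proportions = sort(unique(c(0.5, proportions)), decreasing = TRUE),
    total_size = total_size, models = models, k = as.integer(k),
    n_explain = as.integer(n_explain),
    n_per_class = as.integer(n_per_class %||% (n_explain / 2)),
    lime = lime, shapley_permutations = as.integer(shapley_permutations),
    background_cap = as.integer(background_cap),
    pdp_features = pdp_features, pdp_grid_size = as.integer(pdp_grid_size),
    n_boot = as.integer(n_boot), test_n_per_class = test_n_per_class,
    seed = as.integer(seed)
  ), class = "experiment_config")
}

explain_instances <- function(model, instances, ids, background, config,
                              stage) {
  lime_list <- vector("list", nrow(instances))
  shap_list <- vector("list", nrow(instances))
  for (i in seq_len(nrow(instances))) {
    row <- instances[i, , drop = FALSE]
    cfg <- config$lime
    cfg$seed <- derive_seed(config$seed, paste0(stage, ":lime:", ids[i]))
    lime_list[[i]] <- lime_explain(model, row, background, cfg,
                                   instance_id = ids[i])
    shap_list[[i]] <- shapley_sampled(
      model, row, background,
      n_permutations = config$shapley_permutations,
      seed = derive_seed(config$seed, paste0(stage, ":shap:", ids[i])),
      instance_id = ids[i])
  }
  list(lime = lime_list, shapley = shap_list)
}

#' Run the full imbalance/consistency experiment sweep
#'
#' Generates (or loads) the cohort, performs the stratified split, builds
#' the fixed-size imbalance subsets plus the balanced (50%) reference, and
#' then, for every model in the roster and every condition: fits the model,
#' scores the balanced test sample (AUC plus the Youden operating point),
#' bootstraps the AUC, and explains one shared seeded instance set with LIME
#' and sampled Shapley values. Consistency (overall and class-wise) of each
#' imbalanced condition is computed against the same model's balanced
#' reference, with a Wilcoxon signed-rank test of the paired per-instance
#' values against perfect agreement, and a Mann-Whitney U test comparing
#' bootstrap AUC distributions. Optionally emits partial dependence curves
#' under the balanced and most imbalanced conditions, and writes all results
#' as tidy CSVs plus a JSON manifest when `out_dir` is given. The run is
#' fully deterministic under the config's master seed.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (`NULL` to skip writing).
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly when writing) a list with elements `performance`,
#'   `bootstrap_tests`, `consistency`, `consistency_summary`,
#'   `wilcoxon_tests`, `pdp`, `explanations`, `manifest`.
#' @export
run_sweep <- function(config, out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  cohort <- if (!is.null(config$cohort_csv)) read_cohort(config$cohort_csv)
    else generate_cohort(config$cohort_spec,
                         seed = derive_seed(config$seed, "cohort"))
  say("cohort: %d rows, %d cases", cohort_size(cohort), sum(cohort$outcome))

  sp <- stratified_split(cohort, config$test_fraction,
                         seed = derive_seed(config$seed, "split"))
  n_min_train <- sum(sp$train$outcome)
  total_size <- config$total_size %||% (2L * n_min_train)
  subsets <- make_imbalance_subsets(sp$train, config$proportions, total_size,
                                    seed = derive_seed(config$seed, "subsets"))
  conditions <- names(subsets)
  reference <- conditions[1L] # proportions are sorted decreasing; 0.5 first

  n_test_pc <- min(config$test_n_per_class %||% Inf,
                   min(table(sp$test$outcome)))
  test_bal <- balanced_test_sample(sp$test, n_test_pc,
                                   seed = derive_seed(config$seed, "test"))

  # one shared instance set, stratified by class, explained under every
  # condition — the cross-condition comparisons are per-instance pairings
  pick <- withr::with_seed(derive_seed(config$seed, "instances"), {
    unlist(lapply(c(1L, 0L), function(cl) {
      pool <- which(test_bal$outcome == cl)
      sample(pool, config$n_explain / 2L)
    }), use.names = FALSE)
  })
  instances <- test_bal$data[pick, , drop = FALSE]
  instance_ids <- test_bal$row_id[pick]
  labels <- stats::setNames(test_bal$outcome[pick], as.character(instance_ids))

  adapters <- model_adapter_registry(config$models)
  perf_rows <- list(); boot_rows <- list(); cons_results <- list()
  wilcox_rows <- list(); pdp_rows <- list(); expl_rows <- list()
  boot_auc <- list(); expls <- list()

  for (m in names(adapters)) {
    for (cond in conditions) {
      say("fit %s on %s", m, cond)
      fit <- fit_model(adapters[[m]], subsets[[cond]],
                       seed = derive_seed(config$seed, paste0("fit:", m, ":", cond)))
      scores <- predict_prob(fit, test_bal$data)
      perf_rows[[paste(m, cond)]] <- as.data.frame(
        unclass(performance_summary(scores, test_bal$outcome, m, cond)))
      boot_auc[[paste(m, cond)]] <- bootstrap_metric(
        scores, test_bal$outcome, "auc", config$n_boot,
        seed = derive_seed(config$seed, paste0("boot:", m, ":", cond)))
      bg <- default_background(
        fit, cap = config$background_cap,
        seed = derive_seed(config$seed, paste0("bg:", m, ":", cond)))
      expls[[paste(m, cond)]] <- explain_instances(
        fit, instances, instance_ids, bg, config,
        stage = paste0(m, ":", cond))
      if (!is.null(config$pdp_features) &&
          cond %in% c(reference, conditions[length(conditions)])) {
        for (feat in config$pdp_features) {
          s <- cohort$schema[[feat]]
          curve <- if (s$kind == "continuous") {
            grid <- unique(stats::quantile(
              as.numeric(bg$data[[feat]]),
              probs = seq(0, 1, length.out = config$pdp_grid_size),
              names = FALSE))
            pdp_continuous(fit, bg, feat, sort(grid))
          } else pdp_categorical(fit, bg, feat)
          pdp_rows[[paste(m, cond, feat)]] <- cbind(
            model = m, condition = cond, pdp_to_df(curve))
        }
      }
    }

    ref_expl <- expls[[paste(m, reference)]]
    # a reference-only sweep degenerates to a self-comparison (mean 1.0)
    others <- setdiff(conditions, reference)
    if (!length(others)) others <- reference
    for (cond in others) {
      for (method in c("lime", "shapley")) {
        cmp <- sprintf("%s vs %s", cond, reference)
        prof <- consistency_profile(ref_expl[[method]],
                                    expls[[paste(m, cond)]][[method]],
                                    k = config$k, comparison = cmp)
        cons_results[[paste(m, method, cond)]] <- cbind(
          model = m, method = method, consistency_to_df(list(prof))$summary)
        expl_rows[[paste(m, method, cond, "per")]] <- cbind(
          model = m, method = method,
          consistency_to_df(list(prof))$per_instance)
        cw <- classwise_consistency(
          ref_expl[[method]], expls[[paste(m, cond)]][[method]], labels,
          k = config$k, n_per_class = config$n_per_class,
          seed = derive_seed(config$seed, paste0("classwise:", m, ":", cond)),
          comparison = cmp)
        for (cl in names(cw))
          cons_results[[paste(m, method, cond, cl)]] <- cbind(
            model = m, method = method, consistency_to_df(cw[cl])$summary)
        for (metric in c("jaccard", "rank_agreement")) {
          wt <- wilcoxon_signed_rank(prof$per_instance[[metric]],
                                     rep(1, nrow(prof$per_instance)))
          wilcox_rows[[paste(m, method, cond, metric)]] <- data.frame(
            model = m, method = method, comparison = cmp, metric = metric,
            statistic = wt$statistic, p_value = wt$p_value,
            n = nrow(prof$per_instance), degenerate = wt$degenerate)
        }
      }
      mw <- mann_whitney_u(boot_auc[[paste(m, cond)]],
                           boot_auc[[paste(m, reference)]])
      boot_rows[[paste(m, cond)]] <- data.frame(
        model = m, comparison = sprintf("%s vs %s", cond, reference),
        metric = "auc", statistic = mw$statistic, p_value = mw$p_value,
        n_boot = config$n_boot,
        note = "bootstrap replicates are resamples of one test set, not independent draws")
    }
  }

  manifest <- list(
    seed = config$seed,
    cohort = list(n = cohort_size(cohort), cases = sum(cohort$outcome),
                  source = cohort$source),
    split = list(test_fraction = config$test_fraction,
                 train_cases = sum(sp$train$outcome),
                 test_cases = sum(sp$test$outcome)),
    total_size = total_size,
    conditions = lapply(subsets, function(s)
      list(n = cohort_size(s), cases = sum(s$outcome))),
    reference = reference,
    balanced_test = list(n = cohort_size(test_bal),
                         cases = sum(test_bal$outcome)),
    explained_instances = as.integer(instance_ids),
    models = lapply(adapters, function(a)
      list(label = a$label, params = a$params)),
    explainers = list(lime = unclass(config$lime)[c("n_perturbations",
                                                    "kernel_width",
                                                    "ridge_penalty")],
                      shapley_permutations = config$shapley_permutations,
                      background_cap = config$background_cap),
    k = config$k,
    package_version = as.character(utils::packageVersion("xconsist"))
  )

  out <- list(
    performance = do.call(rbind, perf_rows),
    bootstrap_tests = do.call(rbind, boot_rows),
    consistency = do.call(rbind, expl_rows),
    consistency_summary = do.call(rbind, cons_results),
    wilcoxon_tests = do.call(rbind, wilcox_rows),
    pdp = if (length(pdp_rows)) do.call(rbind, pdp_rows) else NULL,
    manifest = manifest
  )
  rownames(out$performance) <- rownames(out$consistency) <-
    rownames(out$consistency_summary) <- NULL
  if (!is.null(out$bootstrap_tests)) rownames(out$bootstrap_tests) <- NULL
  if (!is.null(out$wilcoxon_tests)) rownames(out$wilcoxon_tests) <- NULL
  if (!is.null(out$pdp)) rownames(out$pdp) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("performance", "bootstrap_tests", "consistency",
                 "consistency_summary", "wilcoxon_tests", "pdp")) {
      if (!is.null(out[[nm]]))
        utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", pretty = TRUE,
                         digits = NA)
    return(invisible(out))
  }
  out
}

#' Default desk-scale sweep configuration
#'
#' The experiment conditions used by the package's own end-to-end analyses:
#' a synthetic primary-care lung-cancer cohort of 40,000 patients with the
#' full feature structure (age, nine-level smoking status, 26 binary
#' flags), minority proportions 40/30/20/10/5/1% plus the balanced
#' reference, subsets of 2,000 rows, gradient-boosted trees, top-10
#' rankings, and 50 shared explained instances (25 per class). The cohort
#' prevalence is raised to 5% so a 40,000-row cohort supplies the minority
#' rows a 40% subset of 2,000 requires; the generator's default 0.6%
#' prevalence is retained wherever prevalence itself is under study.
#'
#' @param seed master seed.
#' @param n_cohort cohort size.
#' @param prevalence synthetic cohort case prevalence for the sweep.
#' @param models adapter names to sweep.
#' @param n_explain shared explained instances (even).
#' @param total_size subset size.
#' @return an [experiment_config()].
#' @export
default_sweep_config <- function(seed = 1L, n_cohort = 40000L,
                                 prevalence = 0.05,
                                 models = "xgboost", n_explain = 50L,
                                 total_size = 2000L) {
  experiment_config(
    cohort_spec = lung_cohort_spec(n = n_cohort,
                                   target_prevalence = prevalence),
    proportions = c(0.4, 0.3, 0.2, 0.1, 0.05, 0.01),
    total_size = total_size, models = models, k = 10L,
    n_explain = n_explain,
    lime = lime_config(n_perturbations = 200L),
    shapley_permutations = 20L, background_cap = 100L,
    pdp_features = c("age", "smoking_status"), pdp_grid_size = 9L,
    n_boot = 100L, test_n_per_class = 400L, seed = seed
  )
}

#' Consistency trend across imbalance severity
#'
#' Extracts, from a sweep result, the mean Jaccard and Rank Agreement of
#' each imbalanced condition against the balanced reference and computes the
#' Spearman correlation between the minority proportion and the mean
#' consistency. A positive correlation means explanations agree less with
#' the balanced reference as imbalance grows.
#'
#' @param results one sweep result or a list of them (e.g. across seeds);
#'   mean consistency is averaged across results per condition first.
#' @param method `"lime"` or `"shapley"`.
#' @param metric `"jaccard"` or `"rank_agreement"`.
#' @return list with `spearman`, and the per-condition `profile` data frame.
#' @export
consistency_trend <- function(results, method = "shapley",
                              metric = "jaccard") {
  if (!is.null(results$consistency_summary)) results <- list(results)
  rows <- do.call(rbind, lapply(results, function(r) {
    s <- r$consistency_summary
    s[s$method == method & s$metric == metric & s$class == "all", ]
  }))
  prop <- as.numeric(sub("%.*", "", rows$comparison)) / 100
  prof <- stats::aggregate(list(mean = rows$mean), list(proportion = prop),
                           mean)
  rho <- stats::cor(prof$proportion, prof$mean, method = "spearman")
  list(spearman = rho, profile = prof)
}

#' Attribution shrinkage under the original imbalance
#'
#' Trains the same model family on (a) the training pool at its original
#' (typically highly imbalanced) class distribution and (b) its
#' random-undersampled balanced counterpart, explains the same minority-class
#' test instances under both, and reports the per-instance mean absolute
#' attribution for each explainer. Because a model trained under heavy
#' imbalance predicts low probabilities for minority instances, the gap
#' between prediction and expected output shrinks, and with it the absolute
#' size of the Shapley values (and, analogously, the LIME coefficients).
#'
#' @param spec cohort spec (default: the lung cohort at 0.6% prevalence).
#' @param model registry adapter name.
#' @param n_instances minority test instances to explain.
#' @param shapley_permutations,lime,background_cap explainer settings.
#' @param seed master seed.
#' @return data frame with one row per instance: predictions and mean
#'   absolute LIME/Shapley attributions under both training conditions.
#' @export
attribution_shrinkage <- function(spec = lung_cohort_spec(n = 40000L),
                                  model = "logistic", n_instances = 35L,
                                  shapley_permutations = 20L,
                                  lime = lime_config(n_perturbations = 200L),
                                  background_cap = 100L, seed = 1L) {
  cohort <- generate_cohort(spec, seed = derive_seed(seed, "cohort"))
  sp <- stratified_split(cohort, 0.2, seed = derive_seed(seed, "split"))
  bal <- undersample_balanced(sp$train, seed = derive_seed(seed, "balance"))
  adapter <- model_adapter_registry(model)[[model]]
  fits <- list(
    original = fit_model(adapter, sp$train,
                         seed = derive_seed(seed, "fit:original")),
    balanced = fit_model(adapter, bal,
                         seed = derive_seed(seed, "fit:balanced"))
  )
  minority <- which(sp$test$outcome == 1L)
  if (length(minority) < 2L) stop("too few minority test instances")
  pick <- withr::with_seed(derive_seed(seed, "pick"),
    sample(minority, min(n_instances, length(minority))))
  out <- lapply(seq_along(pick), function(i) {
    row <- sp$test$data[pick[i], , drop = FALSE]
    id <- sp$test$row_id[pick[i]]
    vals <- lapply(fits, function(fit) {
      bg <- default_background(fit, cap = background_cap,
                               seed = derive_seed(seed, "bg"))
      cfg <- lime
      cfg$seed <- derive_seed(seed, paste0("lime:", id))
      le <- lime_explain(fit, row, bg, cfg, instance_id = id)
      se <- shapley_sampled(fit, row, bg,
                            n_permutations = shapley_permutations,
                            seed = derive_seed(seed, paste0("shap:", id)),
                            instance_id = id)
      c(pred = se$prediction,
        lime = mean(abs(le$attribution)),
        shap = mean(abs(se$attribution)))
    })
    data.frame(instance_id = id,
               pred_original = vals$original[["pred"]],
               pred_balanced = vals$balanced[["pred"]],
               mean_abs_lime_original = vals$original[["lime"]],
               mean_abs_lime_balanced = vals$balanced[["lime"]],
               mean_abs_shap_original = vals$original[["shap"]],
               mean_abs_shap_balanced = vals$balanced[["shap"]],
               row.names = NULL)
  })
  do.call(rbind, out)
}
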