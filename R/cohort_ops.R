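#' Stratified train/test split
#'
#' Splits a cohort so that the case proportion is preserved: within each
#' outcome class, `floor(test_fraction * class_count)` rows are sampled
#' without replacement into the test set and the remainder form the training
#' set. With an 80/20 split of a cohort holding 8,412 cases this yields
#' 6,730 training and 1,682 test cases. Row identities are carried through,
#' so train and test always partition the input.
#'
#' @param cohort a `cohort`.
#' @param test_fraction proportion in (0, 1) routed to the test set.
#' @param seed integer seed.
#' @return a list with elements `train` and `test`, both `cohort` objects.
#' @export
stratified_split <- function(cohort, test_fraction, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"),
            test_fraction > 0, test_fraction < 1)
  counts <- table(factor(cohort$outcome, levels = c(0L, 1L)))
  if (any(counts < 2L))
    stop("each outcome class needs at least 2 rows to split")
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      rows <- which(cohort$outcome == cl)
      n_test <- floor(test_fraction * length(rows))
      if (n_test == 0L) integer(0) else sample(rows, n_test)
    }), use.names = FALSE)
  })
  train_idx <- setdiff(seq_len(cohort_size(cohort)), test_idx)
  list(train = cohort_rows(cohort, sort(train_idx), source = "train"),
       test = cohort_rows(cohort, sort(test_idx), source = "test"))
}

#' Balance a training pool by random undersampling
#'
#' Keeps every minority (case) row and samples an equal number of majority
#' rows without replacement, producing the balanced reference training set.
#'
#' @param train a `cohort`.
#' @param seed integer seed.
#' @return a balanced `cohort` (equal class counts).
#' @export
undersample_balanced <- function(train, seed = 1L) {
  stopifnot(inherits(train, "cohort"))
  minority <- which(train$outcome == 1L)
  majority <- which(train$outcome == 0L)
  if (length(minority) < 1L) stop("no minority rows to balance around")
  if (length(majority) < length(minority))
    stop("majority class smaller than minority; undersampling not applicable")
  keep_maj <- withr::with_seed(seed, sample(majority, length(minority)))
  cohort_rows(train, sort(c(minority, keep_maj)), source = "balanced")
}

#' Fixed-size training subsets at specified minority proportions
#'
#' For each requested proportion, draws a subset of exactly `total_size`
#' rows with `round-half-up(proportion * total_size)` minority rows and the
#' complement in majority rows, both sampled without replacement from the
#' pool. Round-half-up is the convention that maps a 1% proportion of a
#' 13,460-row subset to 135 cases (134.6 rounds up).
#'
#' @param train the training pool (`cohort`).
#' @param proportions numeric vector of minority proportions, each in
#'   (0, 0.5].
#' @param total_size total rows per subset (even).
#' @param seed integer seed; each proportion receives a derived sub-seed.
#' @return a named list of `cohort` objects, names like `"40%"`.
#' @export
make_imbalance_subsets <- function(train, proportions, total_size, seed = 1L) {
  stopifnot(inherits(train, "cohort"), total_size %% 2 == 0)
  if (any(proportions <= 0 | proportions > 0.5))
    stop("proportions must lie in (0, 0.5]")
  minority <- which(train$outcome == 1L)
  majority <- which(train$outcome == 0L)
  out <- lapply(proportions, function(p) {
    n_min <- round_half_up(p * total_size)
    n_maj <- total_size - n_min
    if (n_min < 1L) stop("proportion ", p, " yields an empty minority class")
    if (n_min > length(minority) || n_maj > length(majority))
      stop(sprintf(
        "insufficient pool rows for proportion %g: need %d/%d, have %d/%d",
        p, n_min, n_maj, length(minority), length(majority)))
    sub_seed <- derive_seed(seed, paste0("subset:", format(p)))
    idx <- withr::with_seed(sub_seed, {
      c(sample(minority, n_min), sample(majority, n_maj))
    })
    cohort_rows(train, sort(idx),
                source = sprintf("subset:%g%%", 100 * p))
  })
  names(out) <- sprintf("%g%%", 100 * proportions)
  out
}

#' Training subset with an explicit minority count
#'
#' Companion to [make_imbalance_subsets()] for conditions whose minority
#' count does not follow from round-half-up arithmetic (e.g. an
#' "original distribution" subset whose case count was fixed by the source
#' data rather than by a proportion).
#'
#' @param train the training pool (`cohort`).
#' @param n_minority exact number of minority rows.
#' @param total_size total rows in the subset.
#' @param seed integer seed.
#' @return a `cohort`.
#' @export
make_subset_with_counts <- function(train, n_minority, total_size, seed = 1L) {
  stopifnot(inherits(train, "cohort"), n_minority >= 1,
            total_size > n_minority)
  minority <- which(train$outcome == 1L)
  majority <- which(train$outcome == 0L)
  n_maj <- total_size - n_minority
  if (n_minority > length(minority) || n_maj > length(majority))
    stop("insufficient pool rows for the requested counts")
  idx <- withr::with_seed(seed,
    c(sample(minority, n_minority), sample(majority, n_maj)))
  cohort_rows(train, sort(idx), source = sprintf("subset:%d cases", n_minority))
}

#' Balanced test sample
#'
#' Draws `n_per_class` rows per outcome class from the test cohort without
#' replacement. When `n_per_class` equals the minority test count, every
#' minority row is included.
#'
#' @param test a `cohort`.
#' @param n_per_class rows per class.
#' @param seed integer seed.
#' @return a balanced `cohort` of `2 * n_per_class` rows.
#' @export
balanced_test_sample <- function(test, n_per_class, seed = 1L) {
  stopifnot(inherits(test, "cohort"), n_per_class >= 1)
  idx <- withr::with_seed(seed, {
    unlist(lapply(c(1L, 0L), function(cl) {
      rows <- which(test$outcome == cl)
      if (length(rows) < n_per_class)
        stop(sprintf("class %d has %d rows; %d requested",
                     cl, length(rows), n_per_class))
      if (length(rows) == n_per_class) rows else sample(rows, n_per_class)
    }), use.names = FALSE)
  })
  cohort_rows(test, sort(idx), source = "balanced-test")
}
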