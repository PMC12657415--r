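#' Write a cohort to CSV with a JSON schema sidecar
#'
#' The feature table plus outcome column goes to `path`; feature kinds,
#' declared category levels, the outcome column name and provenance go to a
#' `<path>.schema.json` sidecar so that a round-trip is lossless for both
#' values and type metadata.
#'
#' @param cohort a `cohort` object.
#' @param path CSV file path.
#' @param outcome_col name of the outcome column in the CSV (default
#'   `"outcome"`; must not collide with a feature name).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, outcome_col = "outcome") {
  stopifnot(inherits(cohort, "cohort"))
  if (outcome_col %in% names(cohort$data))
    stop("outcome_col collides with a feature name")
  df <- cohort$data
  for (nm in names(df)) if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
  df[[outcome_col]] <- cohort$outcome
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(
    outcome = outcome_col,
    source = cohort$source,
    seed = cohort$seed,
    features = lapply(cohort$schema, function(s)
      list(name = s$name, kind = s$kind, levels = s$levels))
  )
  jsonlite::write_json(sidecar, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV file path; `<path>.schema.json` must exist alongside it.
#' @return a `cohort` object.
#' @export
read_cohort <- function(path) {
  side_path <- paste0(path, ".schema.json")
  if (!file.exists(side_path)) stop("schema sidecar not found: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  outcome_col <- side$outcome
  if (!outcome_col %in% names(df)) stop("outcome column '", outcome_col,
                                        "' missing from ", path)
  outcome <- df[[outcome_col]]
  df[[outcome_col]] <- NULL
  schema <- lapply(side$features, function(s)
    list(name = s$name, kind = s$kind,
         levels = if (length(s$levels)) unlist(s$levels) else NULL))
  names(schema) <- vapply(schema, `[[`, character(1), "name")
  df <- df[, names(schema), drop = FALSE]
  new_cohort(df, outcome, schema, seed = side$seed,
             source = paste0("file:", path))
}

# subset a cohort by row indices, preserving row identity
cohort_rows <- function(cohort, idx, source = cohort$source) {
  new_cohort(cohort$data[idx, , drop = FALSE], cohort$outcome[idx],
             cohort$schema, spec = cohort$spec, seed = cohort$seed,
             source = source, row_id = cohort$row_id[idx])
}
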