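#' Coverage tables
#'
#' A coverage table is a wide tibble: one row per feature (a taxonomic
#' family or a functional gene family), the metadata columns
#' `feature_id`, `system` and `lineage` first, then one numeric column
#' per sample holding summed read coverage. All table-level verbs in
#' this package (`to_proportions()`, `filter_rare()`, `zscore_table()`,
#' ordination and anomaly fitting) consume and return this shape so
#' stages chain with the pipe.
#'
#' @name coverage-table
NULL

# canonical metadata columns; everything else is a sample column
.meta_cols <- c("feature_id", "system", "lineage",
                "feature_mean", "feature_sd", "retained")

#' Sample columns of a coverage table
#' @param tbl a coverage table
#' @return character vector of sample column names, in table order
#' @export
sample_cols <- function(tbl) {
  setdiff(names(tbl), .meta_cols)
}

#' Extract the numeric feature-by-sample matrix
#'
#' @param tbl a coverage table
#' @return numeric matrix, rownames = `feature_id`, colnames = samples
#' @export
coverage_matrix <- function(tbl) {
  sc <- sample_cols(tbl)
  m <- as.matrix(tbl[, sc, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$feature_id
  m
}

#' Build a coverage table from a matrix
#'
#' @param m numeric feature-by-sample matrix with rownames
#' @param system classification system label (e.g. "family", "KO")
#' @param lineage optional per-feature lineage strings
#' @return a coverage table tibble
#' @export
as_coverage_table <- function(m, system = "feature", lineage = NA_character_) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  tibble::as_tibble(cbind(
    tibble::tibble(feature_id = rownames(m), system = system,
                   lineage = lineage),
    tibble::as_tibble(m, .name_repair = "minimal")
  ))
}

# replace the sample block of `tbl` with matrix `m` (same dim/order)
set_coverage <- function(tbl, m) {
  sc <- sample_cols(tbl)
  stopifnot(ncol(m) == length(sc), nrow(m) == nrow(tbl))
  tbl[, sc] <- tibble::as_tibble(m, .name_repair = "minimal")
  tbl
}
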