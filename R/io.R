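#' Read a coverage table from TSV
#'
#' Expects a header row, the metadata columns (`feature_id`,
#' optionally `system` and `lineage`) first, then numeric sample
#' columns. Lines starting with `#` (provenance headers) are skipped.
#' Any missing or non-numeric cell in the sample block is an error
#' naming its location.
#'
#' @param path TSV file
#' @return a coverage table tibble
#' @export
read_coverage_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  stopifnot("feature_id" %in% names(tbl))
  if (!"system" %in% names(tbl)) tbl$system <- "feature"
  if (!"lineage" %in% names(tbl)) tbl$lineage <- NA_character_
  tbl <- dplyr::relocate(tbl, "feature_id", "system", "lineage")
  sc <- sample_cols(tbl)
  for (cl in sc) {
    v <- tbl[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop("non-numeric value in column '", cl, "', row ",
           if (is.na(bad)) "?" else bad)
    }
    if (anyNA(v)) {
      stop("missing value in column '", cl, "', row ", which(is.na(v))[1])
    }
  }
  tbl
}

#' Write a coverage table to TSV
#'
#' Numeric values are written with 10 significant digits; an optional
#' provenance header (`#`-prefixed, no timestamps so outputs are
#' reproducible byte-for-byte) records the producing stage and seed.
#'
#' @param tbl a coverage table
#' @param path output file
#' @param provenance optional named list recorded in `#` header lines
#' @export
write_coverage_table <- function(tbl, path, provenance = NULL) {
  hdr <- c(
    paste0("# microseasons ",
           as.character(utils::packageVersion("microseasons"))),
    if (!is.null(provenance)) {
      paste0("# ", names(provenance), "=",
             vapply(provenance, function(v) paste(format(v), collapse = ","),
                    character(1)))
    }
  )
  sc <- sample_cols(tbl)
  out <- tbl
  for (cl in sc) out[[cl]] <- formatC(out[[cl]], digits = 10,
                                      format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains the stages end-to-end on simulator output (or tables read
#' from disk): proportion normalisation and rare-feature filtering,
#' z-scoring, per-feature anomaly fits, PCA, MCOA across annotation
#' systems, PERMANOVA, community-aggregated traits, the keyword
#' screen (when annotations are supplied), and the AGS series. All
#' outputs are written as TSV/JSON with provenance headers; runs are
#' byte-identical under a fixed seed.
#'
#' @param config named list: either `sim` (a [sim_config()]) to run on
#'   simulated data, or paths `taxa_table`, `gene_tables` (named list
#'   of TSVs), `markers`, `total_bases`, `dates`; plus `outdir`
#'   (required), `trait_yaml` (optional path; validated before any
#'   computation), `annotations` (optional TSV gene_id/description),
#'   `filter_threshold` (default 5e-5), `n_perm` (default 199),
#'   `seed` (default 42)
#' @return the output directory, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$outdir))
  threshold <- config$filter_threshold %||% 5e-5
  n_perm <- config$n_perm %||% 199
  seed <- config$seed %||% 42
  # validate everything that can fail before computing anything
  if (!is.null(config$trait_yaml) && !file.exists(config$trait_yaml)) {
    stop("config error: trait_yaml does not exist: ", config$trait_yaml)
  }
  for (f in c("taxa_table", "markers", "total_bases", "dates",
              "annotations")) {
    if (!is.null(config[[f]]) && is.character(config[[f]]) &&
        !file.exists(config[[f]])) {
      stop("config error: ", f, " does not exist: ", config[[f]])
    }
  }
  defs <- if (is.null(config$trait_yaml)) read_trait_definitions()
          else read_trait_definitions(config$trait_yaml)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$sim)) {
    sim <- simulate_community(config$sim)
    mk <- simulate_marker_counts(config$sim, community = sim)
    taxa <- sim$taxa; genes <- sim$genes
    markers <- mk$markers; bases <- mk$total_bases
    dates <- sim$dates
  } else {
    taxa <- read_coverage_table(config$taxa_table)
    genes <- lapply(config$gene_tables, read_coverage_table)
    markers <- read_coverage_table(config$markers)
    bases <- readr::read_tsv(config$total_bases, comment = "#",
                             show_col_types = FALSE)
    dates <- readr::read_tsv(config$dates, comment = "#",
                             show_col_types = FALSE)
  }
  dates$date <- as.Date(dates$date)
  prov <- list(seed = seed, filter_threshold = threshold,
               n_perm = n_perm)

  zs <- lapply(c(list(family = taxa), genes), function(tb) {
    tb |> to_proportions() |> filter_rare(threshold) |> zscore_table()
  })
  fits <- lapply(zs, fit_anomaly_table, dates = dates)
  for (nm in names(fits)) {
    write_coverage_table(
      dplyr::rename(fits[[nm]], feature_id = "feature_id") |>
        dplyr::mutate(system = nm, lineage = NA_character_,
                      .after = "feature_id"),
      file.path(config$outdir, paste0("anomaly_", nm, ".tsv")),
      provenance = prov)
  }

  pca_fam <- pca_table(zs$family, mode = "samples")
  readr::write_tsv(pca_fam$scores,
                   file.path(config$outdir, "pca_family_scores.tsv"))
  mc <- mcoa(zs, n_axes = 5)
  readr::write_tsv(mc$scores,
                   file.path(config$outdir, "mcoa_scores.tsv"))

  perm <- permanova(zs$family, data = dates[, c("month", "year")],
                    terms = c("month", "year", "month:year"),
                    n_perm = n_perm, seed = seed)
  jsonlite::write_json(as.list(tibble::as_tibble(perm)),
                       file.path(config$outdir, "permanova.json"),
                       auto_unbox = FALSE, digits = NA)

  gene_cov <- genes[[intersect(c("KO", names(genes)), names(genes))[1]]]
  trait_tbl <- aggregate_traits(dplyr::bind_rows(genes), defs)
  readr::write_tsv(trait_tbl, file.path(config$outdir, "traits.tsv"))
  trait_fits <- lapply(setdiff(names(trait_tbl), "sample"), function(tr) {
    trait_anomalies(tibble::tibble(sample = trait_tbl$sample,
                                   proportion = trait_tbl[[tr]]), dates)
  })
  names(trait_fits) <- setdiff(names(trait_tbl), "sample")

  if (!is.null(config$annotations)) {
    ann <- if (is.character(config$annotations)) {
      readr::read_tsv(config$annotations, comment = "#",
                      show_col_types = FALSE)
    } else config$annotations
    idx <- extract_keywords(ann)
    kw <- keyword_series(idx, to_proportions(gene_cov))
    rk <- rank_keywords(kw, dates, idx)
    readr::write_tsv(dplyr::select(rk$seasonal, -"genes"),
                     file.path(config$outdir, "keywords_seasonal.tsv"))
    readr::write_tsv(dplyr::select(rk$annual, -"genes"),
                     file.path(config$outdir, "keywords_annual.tsv"))
  }

  ags <- ags_series(markers, bases, dates)
  readr::write_tsv(ags$series, file.path(config$outdir, "ags.tsv"))

  jsonlite::write_json(
    c(prov, list(package = "microseasons",
                 version = as.character(utils::packageVersion("microseasons")),
                 systems = names(zs), traits = names(trait_fits))),
    file.path(config$outdir, "provenance.json"), auto_unbox = TRUE)
  invisible(config$outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
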