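#' Annotation keyword index
#'
#' Tokenises free-text gene annotations into keywords: lowercased
#' alphabetic tokens of length >= 3 with stop-words removed, each
#' keyword counted at most once per gene (binary occurrence). Each
#' keyword then behaves like a unit of biodiversity whose abundance
#' is the summed relative abundance of the genes mentioning it.
#'
#' @param annotations tibble with columns `gene_id` and `description`
#' @param stopwords character vector; default the packaged list
#' @return tibble: `keyword`, `gene_id` (one row per pair)
#' @export
extract_keywords <- function(annotations, stopwords = default_stopwords()) {
  stopifnot(all(c("gene_id", "description") %in% names(annotations)),
            nrow(annotations) > 0)
  ann <- annotations[!is.na(annotations$description) &
                       nzchar(trimws(annotations$description)), ]
  toks <- strsplit(tolower(ann$description), "[^a-z]+")
  purrr::map2_dfr(ann$gene_id, toks, function(g, tk) {
    tk <- unique(tk[nchar(tk) >= 3 & !(tk %in% stopwords)])
    if (!length(tk)) return(NULL)
    tibble::tibble(keyword = tk, gene_id = g)
  })
}

#' Packaged stop-word list
#' @return character vector
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords.txt",
                        package = "microseasons"))
}

#' Coverage-weighted keyword time series
#'
#' The value of a keyword in a sample is the sum of the relative
#' proportions of its member genes. Index genes absent from the
#' proportion table are dropped with a warning.
#'
#' @param index keyword-to-gene tibble from [extract_keywords()]
#' @param proportions a proportion table of gene families
#' @return a coverage-table-shaped tibble (`feature_id` = keyword,
#'   `system` = "keyword", one column per sample), ready for
#'   [fit_anomaly_table()]
#' @export
keyword_series <- function(index, proportions) {
  m <- coverage_matrix(proportions)
  missing <- setdiff(unique(index$gene_id), rownames(m))
  if (length(missing)) {
    warning(length(missing), " index gene(s) absent from table, dropped: ",
            paste(utils::head(missing, 5), collapse = ", "))
    index <- index[!(index$gene_id %in% missing), ]
  }
  stopifnot(nrow(index) > 0)
  kw <- rowsum(m[index$gene_id, , drop = FALSE], group = index$keyword)
  as_coverage_table(kw[order(rownames(kw)), , drop = FALSE],
                    system = "keyword")
}

#' Rank keywords by seasonal and annual variance
#'
#' Fits the month + year anomaly model to every keyword series and
#' returns two rankings -- by seasonal (month) and by annual (year)
#' variance fraction of the linear-model sum of squares -- with each
#' keyword's member genes attached for downstream trait curation.
#'
#' @param kw_table keyword series table from [keyword_series()]
#' @param dates tibble mapping `sample` to `date`
#' @param index keyword-to-gene tibble (for the member-gene column)
#' @param top_n rows to keep in each ranking (capped at the number of
#'   keywords)
#' @return list of tibbles `seasonal` and `annual`, each with
#'   `keyword`, the variance fractions, `peak_month`/`peak_year` and
#'   `genes` (list-column)
#' @export
rank_keywords <- function(kw_table, dates, index, top_n = 50) {
  fits <- fit_anomaly_table(kw_table, dates)
  genes <- split(index$gene_id, index$keyword)
  base <- tibble::tibble(
    keyword = fits$feature_id,
    seasonal_fraction = fits$seasonal_fraction,
    annual_fraction = fits$interannual_fraction,
    peak_month = fits$peak_month,
    peak_year = fits$peak_year,
    genes = unname(genes[fits$feature_id])
  )
  n <- min(top_n, nrow(base))
  list(
    seasonal = base |>
      dplyr::arrange(dplyr::desc(.data$seasonal_fraction)) |>
      utils::head(n),
    annual = base |>
      dplyr::arrange(dplyr::desc(.data$annual_fraction)) |>
      utils::head(n)
  )
}
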