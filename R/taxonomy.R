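#' @importFrom rlang .data
NULL

tax_ranks <- c("domain", "phylum", "class", "order", "family",
               "genus", "species")

#' Parse GTDB-style lineage strings
#'
#' Splits semicolon-delimited lineage strings
#' (`d__...;p__...;c__...;o__...;f__...;g__...;s__...`) into the seven
#' canonical ranks. Missing or empty ranks become `"unclassified"`,
#' and the prefix property is enforced: every rank below the first
#' unclassified rank is unclassified.
#'
#' @param x character vector of lineage strings
#' @return tibble with one column per rank
#' @export
parse_lineage <- function(x) {
  parts <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  m <- matrix("unclassified", nrow = length(x), ncol = 7,
              dimnames = list(NULL, tax_ranks))
  for (i in seq_along(parts)) {
    p <- sub("^[dpcofgs]__", "", trimws(parts[[i]]))
    p[p == ""] <- "unclassified"
    k <- min(7, length(p))
    if (k) m[i, seq_len(k)] <- p[seq_len(k)]
  }
  # prefix property
  for (r in 2:7) {
    m[m[, r - 1] == "unclassified", r] <- "unclassified"
  }
  tibble::as_tibble(m)
}

#' Majority-rule consensus taxonomy for contigs
#'
#' Assigns each contig the lineage at the lowest (deepest) taxonomic
#' rank to which at least `threshold` of its open reading frames is
#' assigned. Evaluation proceeds domain to species and stops at the
#' first rank where no taxon reaches the threshold; ranks below the
#' consensus are `"unclassified"`. Unclassified ORFs count in the
#' denominator, diluting support. Ties (two taxa both exactly at
#' threshold) prefer the taxon consistent with the parent-rank
#' consensus, then break lexicographically.
#'
#' @param orfs tibble with columns `contig_id` and `lineage`
#'   (semicolon-delimited string), one row per ORF
#' @param threshold required ORF fraction, in `(0, 1]`; default 0.5
#' @return tibble: `contig_id`, the seven rank columns,
#'   `resolved_rank` (deepest rank reached, or `NA` when wholly
#'   unclassified), `n_orfs`, and `unclassified` flag
#' @export
consensus_lineage <- function(orfs, threshold = 0.5) {
  stopifnot(all(c("contig_id", "lineage") %in% names(orfs)),
            threshold > 0, threshold <= 1, nrow(orfs) > 0)
  ranks <- as.matrix(parse_lineage(orfs$lineage))
  idx <- split(seq_len(nrow(orfs)), orfs$contig_id)
  res <- lapply(idx, function(ii) {
    sub <- ranks[ii, , drop = FALSE]
    n <- length(ii)
    cons <- rep("unclassified", 7)
    depth <- 0L
    for (r in 1:7) {
      vals <- sub[, r]
      tab <- table(vals[vals != "unclassified"])
      if (!length(tab)) break
      cand <- names(tab)[tab / n >= threshold]
      if (!length(cand)) break
      if (length(cand) > 1) {
        if (r > 1) {
          consistent <- vapply(cand, function(t) {
            any(vals == t & sub[, r - 1] == cons[r - 1])
          }, logical(1))
          if (any(consistent)) cand <- cand[consistent]
        }
        cand <- sort(cand)[1]
      }
      cons[r] <- cand
      depth <- r
    }
    c(cons, depth, n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  tibble::tibble(
    contig_id = names(idx),
    !!!stats::setNames(lapply(1:7, function(r) out[, r]), tax_ranks),
    resolved_rank = ifelse(out[, 8] == "0", NA_character_,
                           tax_ranks[as.integer(out[, 8])]),
    n_orfs = as.integer(out[, 9]),
    unclassified = out[, 8] == "0"
  )
}

#' Aggregate contig coverage to a family-level coverage table
#'
#' Sums per-sample contig coverage by consensus family. Contigs not
#' resolved to family rank accumulate under their deepest resolved
#' rank, labelled `"<rank>:<name>_unresolved"`; wholly unclassified
#' contigs under `"unclassified"`.
#'
#' @param consensus output of [consensus_lineage()]
#' @param sample_coverage coverage table whose `feature_id` column
#'   holds contig IDs (one row per contig, columns = samples)
#' @return a family-level coverage table
#' @export
family_table <- function(consensus, sample_coverage) {
  rank_idx <- match(consensus$resolved_rank, tax_ranks)
  label <- vapply(seq_len(nrow(consensus)), function(i) {
    r <- rank_idx[i]
    if (is.na(r)) return("unclassified")
    if (r >= 5) return(consensus$family[i])
    sprintf("%s:%s_unresolved", tax_ranks[r],
            consensus[[tax_ranks[r]]][i])
  }, character(1))
  cov <- coverage_matrix(sample_coverage)
  cov <- cov[match(consensus$contig_id, rownames(cov)), , drop = FALSE]
  agg <- rowsum(cov, group = label)
  as_coverage_table(agg[order(rownames(agg)), , drop = FALSE],
                    system = "family")
}

#' Phylum-level attribution of a gene family
#'
#' For one gene family, sums the coverage of the contigs that carry it
#' by the contigs' consensus phylum and normalises to the across-phylum
#' total, giving per-phylum fractions of that gene's coverage.
#'
#' @param orfs ORF tibble with `contig_id`, `coverage` (contig mean
#'   depth) and one or more annotation columns (`ko`, `pfam`, ...)
#' @param gene_id gene-family ID to profile
#' @param consensus optional pre-computed [consensus_lineage()] output
#' @param threshold consensus threshold when `consensus` is NULL
#' @return tibble: `phylum`, `coverage`, `fraction` (sums to 1)
#' @export
gene_family_phylum_profile <- function(orfs, gene_id, consensus = NULL,
                                       threshold = 0.5) {
  ann_cols <- intersect(c("ko", "pfam", "cog", "tigrfam"), names(orfs))
  hit <- Reduce(`|`, lapply(ann_cols, function(cl) {
    !is.na(orfs[[cl]]) & orfs[[cl]] == gene_id
  }))
  carriers <- unique(orfs$contig_id[hit])
  if (!length(carriers)) {
    warning("gene ", gene_id, " absent from all contigs")
    return(tibble::tibble(phylum = character(), coverage = numeric(),
                          fraction = numeric()))
  }
  if (is.null(consensus)) consensus <- consensus_lineage(orfs, threshold)
  cov <- orfs |>
    dplyr::distinct(.data$contig_id, .data$coverage) |>
    dplyr::filter(.data$contig_id %in% carriers) |>
    dplyr::left_join(consensus[, c("contig_id", "phylum")],
                     by = "contig_id")
  cov |>
    dplyr::group_by(phylum = .data$phylum) |>
    dplyr::summarise(coverage = sum(.data$coverage), .groups = "drop") |>
    dplyr::mutate(fraction = .data$coverage / sum(.data$coverage)) |>
    dplyr::arrange(dplyr::desc(.data$fraction))
}
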