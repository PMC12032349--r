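#' Read trait gene-set definitions from YAML
#'
#' Schema: `trait_name: {system: KO|Pfam, genes: [{id, function}]}`.
#' A small default set covering Fe/N/P nutrient stress and carbon
#' (CAZyme) degradation ships with the package; it is an editable
#' stand-in sufficient for simulation work, not a curated database
#' reproduction.
#'
#' @param path YAML file; default the packaged definitions
#' @return tibble: `trait`, `system`, `gene_id`, `func`
#' @export
read_trait_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "traits.yaml", package = "microseasons")
  }
  raw <- yaml::read_yaml(path)
  purrr::imap_dfr(raw, function(tr, nm) {
    tibble::tibble(
      trait = nm, system = tr$system,
      gene_id = vapply(tr$genes, `[[`, character(1), "id"),
      func = vapply(tr$genes, `[[`, character(1), "function")
    )
  }) |>
    (\(d) { stopifnot(!anyDuplicated(paste(d$trait, d$gene_id))); d })()
}

#' Community-aggregated trait series
#'
#' Sums the coverage of a trait's member gene families per sample and
#' divides by the sample's total annotated coverage, giving the
#' community-aggregated trait proportion. Per-function sub-series
#' (genes grouped by their biochemical function) are attached.
#'
#' @param tbl a coverage table of gene families (raw coverage; the
#'   denominator is its per-sample total)
#' @param definition trait-definition tibble rows (see
#'   [read_trait_definitions()]); a single trait
#' @return tibble of class `trait_series`: `sample`, `proportion`,
#'   with attribute `functions` (tibble sample, func, proportion) and
#'   attribute `trait`
#' @export
aggregate_trait <- function(tbl, definition) {
  stopifnot(length(unique(definition$trait)) == 1)
  m <- coverage_matrix(tbl)
  tot <- colSums(m)
  present <- definition$gene_id %in% rownames(m)
  if (!any(present)) {
    stop("no member gene of trait '", definition$trait[1],
         "' present; missing: ",
         paste(definition$gene_id, collapse = ", "))
  }
  member <- m[definition$gene_id[present], , drop = FALSE]
  series <- colSums(member) / tot
  funcs <- definition$func[present]
  sub <- rowsum(member / rep(tot, each = nrow(member)), group = funcs)
  fun_tbl <- tibble::as_tibble(sub, rownames = "func") |>
    tidyr::pivot_longer(-"func", names_to = "sample",
                        values_to = "proportion")
  structure(
    tibble::tibble(sample = colnames(m), proportion = unname(series)),
    class = c("trait_series", "tbl_df", "tbl", "data.frame"),
    trait = definition$trait[1], functions = fun_tbl,
    missing_members = definition$gene_id[!present]
  )
}

#' Aggregate every trait in a definition table
#'
#' @param tbl a gene-family coverage table
#' @param defs full trait-definition tibble
#' @return tibble: `sample` plus one proportion column per trait
#' @export
aggregate_traits <- function(tbl, defs = read_trait_definitions()) {
  series <- lapply(split(defs, defs$trait), function(d) {
    aggregate_trait(tbl, d)$proportion
  })
  tibble::tibble(sample = sample_cols(tbl), !!!series)
}

#' Anomaly decomposition of a trait series
#'
#' Delegates to [fit_anomaly()] on the trait proportion series and
#' returns the fit with `[-1, 1]`-scaled monthly and yearly effects.
#'
#' @param series a `trait_series` (or tibble with `sample`,
#'   `proportion`)
#' @param dates tibble mapping `sample` to `date`
#' @return an `anomaly_fit`
#' @export
trait_anomalies <- function(series, dates) {
  d <- dplyr::left_join(series, dates[, c("sample", "date")],
                        by = "sample")
  stopifnot(!anyNA(d$date))
  fit_anomaly(d, value = proportion, date = date)
}

#' Spearman correlation of trait and environmental interannual anomalies
#'
#' Correlates each trait's yearly-effect vector with the yearly
#' effects of temperature and of nitrate stress; nitrate stress is
#' defined as `-1 * nitrate`, so the nitrate yearly effects are
#' negated before correlation. Ties take average ranks.
#'
#' @param trait_yearly named numeric vector (one trait) or
#'   traits-x-years matrix of yearly effects
#' @param env_yearly matrix or data frame, years x covariates, with
#'   columns `temperature` and `nitrate` (years aligned with
#'   `trait_yearly`)
#' @return tibble: `trait`, `covariate`, `rho`
#' @export
env_trait_correlation <- function(trait_yearly, env_yearly) {
  if (is.null(dim(trait_yearly))) {
    trait_yearly <- matrix(trait_yearly, nrow = 1,
                           dimnames = list("trait", names(trait_yearly)))
  }
  stopifnot(ncol(trait_yearly) >= 4,
            ncol(trait_yearly) == nrow(env_yearly),
            all(c("temperature", "nitrate") %in% colnames(env_yearly)))
  covs <- cbind(temperature = env_yearly[, "temperature"],
                nitrate_stress = -env_yearly[, "nitrate"])
  purrr::map_dfr(rownames(trait_yearly), function(tr) {
    tibble::tibble(
      trait = tr, covariate = colnames(covs),
      rho = unname(apply(covs, 2, function(v) {
        stats::cor(trait_yearly[tr, ], v, method = "spearman")
      }))
    )
  })
}

#' Pairwise Spearman correlation of trait interannual anomalies
#'
#' Reports how traits co-vary (or anti-vary) across years, e.g.
#' nitrogen stress anti-correlated with iron stress when their
#' carrier guilds respond oppositely to ENSO.
#'
#' @param trait_yearly traits x years matrix of yearly effects
#' @return symmetric matrix of Spearman rho
#' @export
trait_antiphase_report <- function(trait_yearly) {
  stopifnot(nrow(trait_yearly) >= 2)
  stats::cor(t(trait_yearly), method = "spearman")
}
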