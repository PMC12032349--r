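#' Average genome size from single-copy marker genes
#'
#' The community average genome size (AGS) of a sample is the total
#' assembled bases divided by the estimated number of genomes, the
#' latter taken as the mean of the coverage-weighted counts of the
#' 139 universal single-copy marker genes (markers absent from the
#' assembly count as zero, inflating the dispersion). When the
#' coefficient of variation across markers (sd/mean) is >= 0.5 the
#' estimate is flagged unreliable and no AGS is reported.
#'
#' @param marker_counts numeric vector of per-marker coverage-weighted
#'   counts (one value per marker gene)
#' @param total_bases total assembled bases of the sample
#' @return one-row tibble: `n_genomes`, `cv`, `reliable`, `ags`
#'   (`NA` when unreliable)
#' @export
estimate_ags <- function(marker_counts, total_bases) {
  stopifnot(total_bases > 0, length(marker_counts) >= 1)
  if (all(marker_counts == 0)) stop("all marker counts are zero")
  n_genomes <- mean(marker_counts)
  cv <- stats::sd(marker_counts) / n_genomes
  if (length(marker_counts) == 1) cv <- 0
  reliable <- cv < 0.5
  tibble::tibble(
    n_genomes = unname(n_genomes), cv = unname(cv), reliable = reliable,
    ags = if (reliable) unname(total_bases / n_genomes) else NA_real_
  )
}

#' Per-sample AGS series with anomaly decomposition
#'
#' Applies [estimate_ags()] to every sample and fits the month + year
#' anomaly model to the AGS series over the reliable samples.
#'
#' @param markers coverage table of marker counts (rows = markers,
#'   columns = samples)
#' @param total_bases tibble `sample`, `bases`
#' @param dates tibble mapping `sample` to `date`
#' @return list: `series` (tibble sample, date, n_genomes, cv,
#'   reliable, ags), `fit` (an `anomaly_fit` over reliable samples),
#'   `n_unreliable`
#' @export
ags_series <- function(markers, total_bases, dates) {
  m <- coverage_matrix(markers)
  bases <- total_bases$bases[match(colnames(m), total_bases$sample)]
  stopifnot(!anyNA(bases))
  est <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    estimate_ags(m[, j], bases[j])
  })
  series <- dplyr::bind_cols(
    tibble::tibble(sample = colnames(m),
                   date = as.Date(dates$date[match(colnames(m),
                                                   dates$sample)])),
    est
  )
  ok <- series$reliable
  if (!any(ok)) stop("no reliable sample; cannot fit AGS series")
  fit <- if (length(unique(format(series$date[ok], "%Y"))) >= 2 &&
             length(unique(format(series$date[ok], "%m"))) >= 2) {
    fit_anomaly(series[ok, ], value = ags, date = date)
  } else NULL
  list(series = series, fit = fit, n_unreliable = sum(!ok))
}
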