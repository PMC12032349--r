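#' Convert coverage to relative proportions
#'
#' Divides every sample column by its summed total coverage, so each
#' sample's proportions over all features sum to one. The totals are
#' stored in the `sample_totals` attribute so original coverage is
#' recoverable.
#'
#' @param tbl a coverage table
#' @return a proportion table (same shape) with attribute
#'   `sample_totals`
#' @export
to_proportions <- function(tbl) {
  m <- coverage_matrix(tbl)
  tot <- colSums(m)
  if (any(tot <= 0)) {
    stop("zero total coverage in sample(s): ",
         paste(colnames(m)[tot <= 0], collapse = ", "))
  }
  out <- set_coverage(tbl, sweep(m, 2, tot, "/"))
  attr(out, "sample_totals") <- tot
  out
}

#' Drop rare features
#'
#' Excludes features whose mean relative proportion across samples is
#' below `threshold` (boundary inclusive: a feature exactly at the
#' threshold is retained). Dropped feature IDs are kept in the
#' `dropped_features` attribute for provenance.
#'
#' @param tbl a proportion table
#' @param threshold minimum mean proportion; default 5e-5
#' @return the filtered proportion table
#' @export
filter_rare <- function(tbl, threshold = 5e-5) {
  stopifnot(threshold >= 0)
  m <- coverage_matrix(tbl)
  keep <- rowMeans(m) >= threshold
  out <- tbl[keep, , drop = FALSE]
  attr(out, "sample_totals") <- attr(tbl, "sample_totals")
  attr(out, "dropped_features") <- tbl$feature_id[!keep]
  out
}

#' Z-score features across samples
#'
#' Standardises each feature's proportion series to mean zero and unit
#' standard deviation (sample sd, `n - 1` denominator). Zero-variance
#' features are excluded and listed in the `constant_features`
#' attribute. With `log = TRUE` the proportions are log-transformed
#' first (zeros replaced by half the smallest positive value), the
#' natural scale when abundances follow a log-linear seasonal model.
#'
#' @param tbl a proportion (or coverage) table with >= 2 samples
#' @param log log-transform before standardising
#' @return a z-score table with extra columns `feature_mean` and
#'   `feature_sd` holding the statistics used
#' @export
zscore_table <- function(tbl, log = FALSE) {
  m <- coverage_matrix(tbl)
  if (log) {
    pos <- min(m[m > 0])
    m[m == 0] <- pos / 2
    m <- base::log(m)
  }
  if (ncol(m) < 2) stop("need at least two samples to z-score")
  mu <- rowMeans(m)
  sd_ <- apply(m, 1, stats::sd)
  const <- sd_ == 0 | !is.finite(sd_)
  if (any(const)) {
    warning(sum(const), " zero-variance feature(s) excluded")
  }
  z <- (m[!const, , drop = FALSE] - mu[!const]) / sd_[!const]
  out <- set_coverage(tbl[!const, , drop = FALSE], z)
  out <- dplyr::mutate(out, feature_mean = mu[!const],
                       feature_sd = sd_[!const],
                       .after = dplyr::any_of(c("lineage", "system",
                                                "feature_id"))[1])
  attr(out, "constant_features") <- tbl$feature_id[const]
  out
}

#' Robust loess smoothing
#'
#' Locally weighted linear regression with tricube weights and
#' iterated bisquare robustness reweighting (3 iterations), the
#' standard robust lowess smoother, used here as the low-frequency
#' band-pass filter for time-series presentation.
#'
#' @param x ordinate (e.g. numeric date); must be sortable
#' @param y series to smooth
#' @param span fraction of points in each local window, in `(0, 1]`
#' @param iter robustness iterations
#' @return numeric vector of smoothed values aligned with the input
#'   order of `x`
#' @export
robust_loess <- function(x, y, span = 0.3, iter = 3) {
  stopifnot(length(x) == length(y), span > 0, span <= 1,
            length(x) >= max(5, ceiling(span * length(x))))
  x <- as.numeric(x)
  fit <- suppressWarnings(stats::loess(
    y ~ x, span = span, degree = 1, family = "symmetric",
    control = stats::loess.control(surface = "direct",
                                   iterations = iter + 1)))
  unname(stats::predict(fit, newdata = data.frame(x = x)))
}
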