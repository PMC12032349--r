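#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an anomaly fit
#'
#' @param x an `anomaly_fit`
#' @param ... unused
#' @return tibble: `term` (`month_01`.. / `year_<y>`), `effect`,
#'   `scaled`
#' @export
tidy.anomaly_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = sprintf("month_%02d", 1:12),
                   effect = unname(x$monthly_effects),
                   scaled = unname(x$scaled_monthly)),
    tibble::tibble(term = paste0("year_", names(x$yearly_effects)),
                   effect = unname(x$yearly_effects),
                   scaled = unname(x$scaled_yearly))
  )
}

#' @rdname tidy.anomaly_fit
#' @export
glance.anomaly_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, intercept = x$intercept,
    ss_month = x$ss_month, ss_year = x$ss_year,
    ss_residual = x$ss_residual, ss_total = x$ss_total,
    seasonal_fraction = x$ss_month / x$ss_total,
    interannual_fraction = x$ss_year / x$ss_total,
    peak_month = x$peak_month, peak_year = x$peak_year
  )
}

#' Tidy ordination results
#'
#' @param x an `ms_pca` or `ms_mcoa`
#' @param ... unused
#' @return tibble: one row per axis with (pseudo-)eigenvalue and
#'   variance fraction
#' @export
tidy.ms_pca <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = x$variance_fraction)
}

#' @rdname tidy.ms_pca
#' @export
tidy.ms_mcoa <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$pseudo_eig),
                 pseudo_eigenvalue = x$pseudo_eig,
                 variance_fraction = x$variance_fraction)
}

#' @rdname tidy.ms_pca
#' @export
tidy.ms_permanova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.ms_pca
#' @export
glance.ms_permanova <- function(x, ...) {
  terms <- x$term[!(x$term %in% c("Residual", "Total"))]
  tibble::tibble(
    n_terms = length(terms),
    r_squared_model = sum(x$r_squared[x$term %in% terms]),
    n_perm = attr(x, "n_perm"), seed = attr(x, "seed")
  )
}
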