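#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of scaled seasonal anomalies, features ordered by peak month
#'
#' @param object an `anomaly_fits` tibble
#' @param by order features by `"month"` or `"year"` peak
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.anomaly_fits <- function(object, by = "month", ...) {
  ord <- order_by_peak(object, by = by)
  long <- ord |>
    dplyr::select("feature_id", dplyr::matches("^m\\d{2}$")) |>
    tidyr::pivot_longer(-"feature_id", names_to = "month",
                        values_to = "effect") |>
    dplyr::mutate(month = as.integer(sub("^m", "", .data$month))) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::mutate(effect = scale_anomaly(.data$effect)) |>
    dplyr::ungroup() |>
    dplyr::mutate(feature_id = factor(.data$feature_id,
                                      levels = rev(ord$feature_id)))
  ggplot2::ggplot(long, ggplot2::aes(.data$month, .data$feature_id,
                                     fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b",
                                  limits = c(-1, 1)) +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::labs(x = "Month", y = NULL, fill = "Scaled\nanomaly") +
    ggplot2::theme_minimal()
}

#' Ordination score plot
#'
#' @param object an `ms_pca` or `ms_mcoa` result
#' @param colour optional vector (e.g. collection month) colouring
#'   the points, aligned with the score rows
#' @param axes which two axes to draw
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.ms_pca <- function(object, colour = NULL, axes = c(1, 2), ...) {
  sc <- object$scores
  ax <- names(sc)[-1][axes]
  lab <- sprintf("%s (%.1f%%)", ax, 100 * object$variance_fraction[axes])
  df <- dplyr::mutate(sc, .colour = colour %||% "sample")
  ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                   colour = .data$.colour)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab[1], y = lab[2], colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ms_pca
#' @export
autoplot.ms_mcoa <- function(object, colour = NULL, axes = c(1, 2), ...) {
  sc <- object$scores
  ax <- names(sc)[-1][axes]
  lab <- sprintf("%s (%.1f%%)", ax, 100 * object$variance_fraction[axes])
  df <- dplyr::mutate(sc, .colour = colour %||% "sample")
  ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                   colour = .data$.colour)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab[1], y = lab[2], colour = NULL) +
    ggplot2::theme_minimal()
}

#' Seasonal and interannual anomaly profile of one fit
#'
#' @param object an `anomaly_fit`
#' @param ... unused
#' @return a ggplot (two panels: monthly and yearly scaled effects)
#' @export
autoplot.anomaly_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(panel = "seasonal", level = 1:12,
                   effect = object$scaled_monthly),
    tibble::tibble(panel = "interannual",
                   level = as.integer(names(object$yearly_effects)),
                   effect = object$scaled_yearly)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$level, .data$effect)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Scaled anomaly") +
    ggplot2::theme_minimal()
}
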