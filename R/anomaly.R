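#' Seasonal/interannual anomaly decomposition
#'
#' Each time series is decomposed by ordinary least squares on an
#' additive model with month (12 levels, the seasonal anomaly) and
#' year (one level per observed year, the interannual anomaly) as
#' categorical factors and no interaction, under sum-to-zero (effects)
#' coding, so every effect is a deviation from the grand mean on the
#' response's own scale. Sums of squares are sequential (Type I),
#' month entered first by default since the seasonal signal dominates
#' these series; the order is configurable.
#'
#' @name anomaly-model
NULL

# shared OLS core: Y is an n x q response matrix; returns effects and
# sequential SS for all q series in one QR factorisation
fit_anomaly_core <- function(Y, month, year, order = c("month", "year")) {
  order <- match.arg(order, c("month", "year"), several.ok = TRUE)
  n <- nrow(Y)
  stopifnot(length(month) == n, length(year) == n)
  obs_m <- sort(unique(as.integer(month)))
  obs_y <- sort(unique(as.integer(year)))
  if (length(obs_m) < 2 || length(obs_y) < 2) {
    stop("need >= 2 distinct months and >= 2 distinct years")
  }
  if (length(obs_m) < 12) {
    warning("month level(s) with no observations dropped: ",
            paste(setdiff(1:12, obs_m), collapse = ", "))
  }
  mf <- factor(month, levels = obs_m)
  yf <- factor(year, levels = obs_y)
  Cm <- stats::contr.sum(length(obs_m))
  Cy <- stats::contr.sum(length(obs_y))
  Xm <- Cm[as.integer(mf), , drop = FALSE]
  Xy <- Cy[as.integer(yf), , drop = FALSE]
  blocks <- list(month = Xm, year = Xy)[order]
  X <- cbind(1, blocks[[1]], blocks[[2]])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("month and year factors are confounded; effects not estimable")
  }
  Qty <- qr.qty(qrX, Y)
  coefs <- qr.coef(qrX, Y)
  k1 <- ncol(blocks[[1]]); k2 <- ncol(blocks[[2]])
  ss_block <- function(rows) colSums(Qty[rows, , drop = FALSE]^2)
  ss1 <- ss_block(1 + seq_len(k1))
  ss2 <- ss_block(1 + k1 + seq_len(k2))
  ss_resid <- if (qrX$rank < n) {
    colSums(Qty[(qrX$rank + 1):n, , drop = FALSE]^2)
  } else rep(0, ncol(Y))
  ss <- stats::setNames(list(ss1, ss2), names(blocks))

  eff <- function(block, C_, obs, full_levels) {
    rows <- if (block == names(blocks)[1]) 1 + seq_len(k1)
            else 1 + k1 + seq_len(k2)
    e <- C_ %*% coefs[rows, , drop = FALSE]      # observed levels x q
    out <- matrix(NA_real_, length(full_levels), ncol(Y),
                  dimnames = list(full_levels, colnames(Y)))
    out[match(obs, full_levels), ] <- e
    out
  }
  monthly <- eff("month", Cm, obs_m, 1:12)
  yearly <- eff("year", Cy, obs_y, obs_y)
  list(intercept = coefs[1, ], monthly = monthly, yearly = yearly,
       ss_month = ss$month, ss_year = ss$year, ss_resid = ss_resid,
       ss_total = ss$month + ss$year + ss_resid,
       fitted = X %*% coefs, obs_years = obs_y, order = order)
}

#' Fit the month + year anomaly model to one series
#'
#' @param data data frame with at least a date column and a value
#'   column (dates as `Date`; month/year are derived from them)
#' @param value,date tidy-selected columns holding the response and
#'   the sampling date
#' @param order which factor enters the sequential SS first
#' @return an object of class `anomaly_fit`: intercept, 12
#'   `monthly_effects` (sum-to-zero; `NA` for unobserved months),
#'   `yearly_effects` (named by year), residuals, the SS partition,
#'   `peak_month`, `peak_year`, and `[-1, 1]`-scaled effects
#' @export
fit_anomaly <- function(data, value, date = date,
                        order = c("month", "year")) {
  y <- dplyr::pull(data, {{ value }})
  d <- dplyr::pull(data, {{ date }})
  stopifnot(!anyNA(y), !anyNA(d))
  month <- as.integer(format(as.Date(d), "%m"))
  year <- as.integer(format(as.Date(d), "%Y"))
  core <- fit_anomaly_core(matrix(y, ncol = 1), month, year, order)
  monthly <- drop(core$monthly)
  yearly <- drop(core$yearly)
  names(yearly) <- core$obs_years
  structure(list(
    intercept = unname(core$intercept),
    monthly_effects = monthly, yearly_effects = yearly,
    residuals = y - drop(core$fitted),
    ss_month = unname(core$ss_month), ss_year = unname(core$ss_year),
    ss_residual = unname(core$ss_resid), ss_total = unname(core$ss_total),
    peak_month = if (all(is.na(monthly))) NA_integer_
                 else unname(which.max(monthly)),
    peak_year = core$obs_years[which.max(yearly)],
    scaled_monthly = scale_anomaly(monthly),
    scaled_yearly = scale_anomaly(yearly),
    n = length(y), order = core$order
  ), class = "anomaly_fit")
}

#' @export
print.anomaly_fit <- function(x, ...) {
  cat("<anomaly_fit> n =", x$n, " peak month", x$peak_month,
      " peak year", x$peak_year, "\n")
  fr <- variance_fractions(x)
  cat(sprintf("  variance: seasonal %.1f%%, interannual %.1f%%, residual %.1f%%\n",
              100 * fr$seasonal, 100 * fr$interannual, 100 * fr$residual))
  invisible(x)
}

#' Fit the anomaly model to every feature of a z-score table
#'
#' One QR factorisation fits all features simultaneously.
#'
#' @param tbl a z-score (or proportion) table
#' @param dates tibble mapping `sample` to `date` (as produced by the
#'   simulator), or a `Date` vector ordered as the sample columns
#' @param order which factor enters the sequential SS first
#' @return tibble of class `anomaly_fits`: one row per feature with
#'   `intercept`, `m01`..`m12`, `y<year>` columns, SS partition,
#'   variance fractions, `peak_month`, `peak_year`
#' @export
fit_anomaly_table <- function(tbl, dates, order = c("month", "year")) {
  m <- coverage_matrix(tbl)
  d <- if (is.data.frame(dates)) {
    as.Date(dates$date[match(colnames(m), dates$sample)])
  } else as.Date(dates)
  stopifnot(!anyNA(d), length(d) == ncol(m))
  month <- as.integer(format(d, "%m"))
  year <- as.integer(format(d, "%Y"))
  core <- fit_anomaly_core(t(m), month, year, order)
  monthly <- t(core$monthly)                  # q x 12
  yearly <- t(core$yearly)
  colnames(monthly) <- sprintf("m%02d", 1:12)
  colnames(yearly) <- paste0("y", core$obs_years)
  out <- tibble::tibble(
    feature_id = rownames(m),
    intercept = unname(core$intercept),
    !!!tibble::as_tibble(monthly), !!!tibble::as_tibble(yearly),
    ss_month = unname(core$ss_month), ss_year = unname(core$ss_year),
    ss_residual = unname(core$ss_resid),
    ss_total = unname(core$ss_total),
    seasonal_fraction = unname(core$ss_month / core$ss_total),
    interannual_fraction = unname(core$ss_year / core$ss_total),
    peak_month = apply(monthly, 1, function(v) {
      if (all(is.na(v))) NA_integer_ else which.max(v)
    }),
    peak_year = core$obs_years[apply(yearly, 1, which.max)]
  )
  structure(out, class = c("anomaly_fits", class(out)),
            obs_years = core$obs_years)
}

#' Scale anomalies to \[-1, 1\]
#'
#' Divides effects by the maximum absolute effect; an all-zero vector
#' is returned unchanged.
#'
#' @param effects numeric vector of fitted effects
#' @return scaled vector with `max(abs(.)) == 1`, or all zeros
#' @export
scale_anomaly <- function(effects) {
  m <- max(abs(effects), na.rm = TRUE)
  if (!is.finite(m) || m == 0) return(effects)
  effects / m
}

#' Variance fractions of an anomaly fit
#'
#' @param fit an `anomaly_fit` or `anomaly_fits` object
#' @return tibble with `seasonal`, `interannual`, `residual` fractions
#'   (summing to 1), one row per series
#' @export
variance_fractions <- function(fit) {
  UseMethod("variance_fractions")
}

#' @export
variance_fractions.anomaly_fit <- function(fit) {
  if (fit$ss_total <= 1e-12 * fit$n * (fit$intercept^2 + 1)) {
    stop("constant series: variance fractions undefined")
  }
  tibble::tibble(seasonal = fit$ss_month / fit$ss_total,
                 interannual = fit$ss_year / fit$ss_total,
                 residual = fit$ss_residual / fit$ss_total)
}

#' @export
variance_fractions.anomaly_fits <- function(fit) {
  tibble::tibble(feature_id = fit$feature_id,
                 seasonal = fit$ss_month / fit$ss_total,
                 interannual = fit$ss_year / fit$ss_total,
                 residual = fit$ss_residual / fit$ss_total)
}

# circular phase (in months, 0-12) of the first harmonic of a
# 12-vector of monthly effects; secondary sort key for peak ties
monthly_phase <- function(eff) {
  m <- 1:12
  ok <- !is.na(eff)
  ang <- atan2(sum(eff[ok] * sin(2 * pi * m[ok] / 12)),
               sum(eff[ok] * cos(2 * pi * m[ok] / 12)))
  (ang %% (2 * pi)) * 12 / (2 * pi)
}

#' Order features by anomaly peak
#'
#' Sorts the rows of an `anomaly_fits` table by peak month (or peak
#' year); ties are broken by the circular phase of a first-harmonic
#' cosine fit to the monthly effects.
#'
#' @param fits an `anomaly_fits` tibble
#' @param by `"month"` or `"year"`
#' @return the reordered `anomaly_fits` tibble
#' @export
order_by_peak <- function(fits, by = c("month", "year")) {
  by <- match.arg(by)
  stopifnot(nrow(fits) > 0)
  mm <- as.matrix(fits[, sprintf("m%02d", 1:12)])
  phase <- apply(mm, 1, monthly_phase)
  key <- if (by == "month") fits$peak_month else fits$peak_year
  fits[order(key, phase), , drop = FALSE]
}

#' Interannual variance explained by environmental covariates
#'
#' Regresses each feature's yearly-effect vector on the environmental
#' yearly effects (OLS with intercept) and reports the pooled fraction
#' of interannual variance explained: summed explained SS over summed
#' total SS across features, a redundancy-style statistic.
#'
#' @param feature_yearly features x years matrix (or `anomaly_fits`
#'   tibble, whose `y<year>` columns are used)
#' @param env_yearly years x covariates matrix of environmental yearly
#'   effects (e.g. temperature and nitrate columns)
#' @return list: `fraction` (pooled), `per_feature` tibble of R^2
#' @export
env_variance_explained <- function(feature_yearly, env_yearly) {
  if (inherits(feature_yearly, "anomaly_fits")) {
    ycols <- grep("^y\\d{4}$", names(feature_yearly), value = TRUE)
    ids <- feature_yearly$feature_id
    feature_yearly <- as.matrix(feature_yearly[, ycols])
    rownames(feature_yearly) <- ids
  }
  env_yearly <- as.matrix(env_yearly)
  stopifnot(ncol(env_yearly) >= 2, ncol(feature_yearly) >= 4,
            ncol(feature_yearly) == nrow(env_yearly))
  X <- cbind(1, env_yearly)
  if (qr(X)$rank < ncol(X)) stop("environmental covariates are collinear")
  Y <- t(feature_yearly)                       # years x features
  fit <- stats::lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  ss_res <- colSums(res^2)
  ss_tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
  ok <- ss_tot > 0
  list(
    fraction = sum(ss_tot[ok] - ss_res[ok]) / sum(ss_tot[ok]),
    per_feature = tibble::tibble(
      feature_id = colnames(Y),
      r_squared = ifelse(ok, 1 - ss_res / ss_tot, NA_real_))
  )
}
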