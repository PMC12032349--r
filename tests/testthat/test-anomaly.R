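# balanced 4-year monthly design used in several blocks
balanced_dates <- function(n_years = 4) {
  as.Date(sprintf("%d-%02d-15", rep(2011:(2010 + n_years), each = 12),
                  rep(1:12, n_years)))
}

test_that("constant and single-month-pulse series decompose as forced", {
  d <- balanced_dates()
  flat <- tibble::tibble(date = d, value = 3)
  f <- fit_anomaly(flat, value)
  expect_equal(unname(f$monthly_effects), rep(0, 12), tolerance = 1e-12)
  expect_equal(unname(f$yearly_effects), rep(0, 4), tolerance = 1e-12)
  expect_equal(f$ss_residual, 0, tolerance = 1e-12)
  expect_equal(f$intercept, 3)

  pulse <- tibble::tibble(date = d,
                          value = ifelse(format(d, "%m") == "07", 1, -1))
  fp <- fit_anomaly(pulse, value)
  expect_equal(fp$peak_month, 7L)
  expect_equal(max(fp$monthly_effects), unname(fp$monthly_effects[7]))
  expect_equal(variance_fractions(fp)$seasonal, 1, tolerance = 1e-12)
})

test_that("effects equal the pseudo-inverse OLS oracle on random toys", {
  set.seed(41)
  d <- balanced_dates(4)           # n = 48
  for (i in 1:5) {
    y <- rnorm(48)
    f <- fit_anomaly(tibble::tibble(date = d, value = y), value)
    o <- oracle_anomaly_ols(y, as.integer(format(d, "%m")),
                            as.integer(format(d, "%Y")))
    expect_equal(unname(f$monthly_effects), o$monthly, tolerance = 1e-8)
    expect_equal(unname(f$yearly_effects), o$yearly, tolerance = 1e-8)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-8)
  }
  # unbalanced design: drop a third of the points
  keep <- sort(sample(48, 32))
  y <- rnorm(48)[keep]; du <- d[keep]
  f <- fit_anomaly(tibble::tibble(date = du, value = y), value)
  o <- oracle_anomaly_ols(y, as.integer(format(du, "%m")),
                          as.integer(format(du, "%Y")))
  expect_equal(unname(f$monthly_effects)[o$months], o$monthly,
               tolerance = 1e-8)
  expect_equal(unname(f$yearly_effects), o$yearly, tolerance = 1e-8)
})

test_that("effects sum to zero and SS partition is exact", {
  set.seed(42)
  d <- balanced_dates(4)[sort(sample(48, 40))]
  y <- rnorm(40)
  f <- fit_anomaly(tibble::tibble(date = d, value = y), value)
  expect_lt(abs(sum(f$monthly_effects, na.rm = TRUE)), 1e-9)
  expect_lt(abs(sum(f$yearly_effects)), 1e-9)
  expect_equal(f$ss_month + f$ss_year + f$ss_residual, f$ss_total,
               tolerance = 1e-6)
  expect_equal(f$ss_total, sum((y - mean(y))^2), tolerance = 1e-8)
  fr <- variance_fractions(f)
  expect_equal(fr$seasonal + fr$interannual + fr$residual, 1,
               tolerance = 1e-12)
})

test_that("balanced-design monthly effects equal month means minus grand mean", {
  set.seed(43)
  d <- balanced_dates(6)
  y <- rnorm(72)
  f <- fit_anomaly(tibble::tibble(date = d, value = y), value)
  mm <- tapply(y, format(d, "%m"), mean) - mean(y)
  expect_equal(unname(f$monthly_effects), as.numeric(mm),
               tolerance = 1e-10)
})

test_that("adding a constant shifts only the intercept", {
  set.seed(44)
  d <- balanced_dates(3)
  y <- rnorm(36)
  f1 <- fit_anomaly(tibble::tibble(date = d, value = y), value)
  f2 <- fit_anomaly(tibble::tibble(date = d, value = y + 10), value)
  expect_equal(f2$intercept, f1$intercept + 10, tolerance = 1e-10)
  expect_equal(f2$monthly_effects, f1$monthly_effects, tolerance = 1e-10)
  expect_equal(f2$yearly_effects, f1$yearly_effects, tolerance = 1e-10)
})

test_that("scale_anomaly maps to [-1, 1] and skips all-zero input", {
  expect_equal(scale_anomaly(c(2, -4, 0)), c(0.5, -1, 0))
  expect_equal(scale_anomaly(rep(0, 5)), rep(0, 5))
  set.seed(45)
  for (i in 1:20) {
    s <- scale_anomaly(rnorm(12))
    expect_equal(max(abs(s)), 1, tolerance = 1e-12)
  }
})

test_that("features are ordered by peak month with circular-phase ties", {
  cfg <- small_sim(seasonal_amplitude = 2, noise_sd = 0.2,
                   seasonal_peak_month = c(10, 3, 7, 1, 5, 12, 8, 4))
  sim <- simulate_community(cfg, systems = character(0))
  z <- sim$taxa |> to_proportions() |> zscore_table(log = TRUE)
  fits <- fit_anomaly_table(z, sim$dates)
  ord <- order_by_peak(fits, by = "month")
  got <- cfg$seasonal_peak_month[match(ord$feature_id, cfg$taxon_id)]
  expect_equal(got, sort(got))
  expect_equal(nrow(order_by_peak(fits[1, ])), 1)
})

test_that("variance fractions refuse a constant series", {
  d <- balanced_dates(2)
  f <- fit_anomaly(tibble::tibble(date = d, value = 1), value)
  expect_error(variance_fractions(f), "constant")
})

test_that("iid-noise seasonal fraction matches a direct OLS SS oracle", {
  set.seed(46)
  d <- balanced_dates(10)
  y <- rnorm(120)
  f <- fit_anomaly(tibble::tibble(date = d, value = y), value)
  a <- stats::anova(stats::lm(y ~ factor(format(d, "%m")) +
                                factor(format(d, "%Y"))))
  expect_equal(variance_fractions(f)$seasonal,
               a$`Sum Sq`[1] / sum(a$`Sum Sq`), tolerance = 1e-8)
  expect_equal(variance_fractions(f)$interannual,
               a$`Sum Sq`[2] / sum(a$`Sum Sq`), tolerance = 1e-8)
})

test_that("env_variance_explained brackets exact and orthogonal cases", {
  set.seed(47)
  ny <- 8
  env <- cbind(temperature = rnorm(ny), nitrate = rnorm(ny))
  # features built exactly from the covariates -> fraction 1
  B <- matrix(rnorm(2 * 30), 2)
  feat <- t(env %*% B)
  colnames(feat) <- paste0("y", 2011:2018)
  rownames(feat) <- paste0("f", 1:30)
  ev <- env_variance_explained(feat, env)
  expect_equal(ev$fraction, 1, tolerance = 1e-8)
  # covariates orthogonal to every feature -> fraction 0
  feat2 <- matrix(rnorm(30 * ny), 30)
  Q <- qr.Q(qr(cbind(1, env)))
  feat2 <- feat2 - feat2 %*% Q %*% t(Q)
  rownames(feat2) <- paste0("f", 1:30)
  ev2 <- env_variance_explained(feat2, env)
  expect_equal(ev2$fraction, 0, tolerance = 1e-8)
  # collinear covariates refused
  expect_error(env_variance_explained(feat, cbind(env[, 1], env[, 1] * 2)),
               "collinear")
})

test_that("injected env-driven interannual variance is recovered", {
  set.seed(48)
  ny <- 12; nf <- 200
  env <- cbind(temperature = rnorm(ny), nitrate = rnorm(ny))
  B <- matrix(rnorm(2 * nf), 2)
  signal <- env %*% B                       # years x features
  noise <- matrix(rnorm(ny * nf), ny)
  # scale so env-driven share is 50% on average
  signal <- signal / sqrt(mean(apply(signal, 2, var)))
  noise <- noise / sqrt(mean(apply(noise, 2, var)))
  feat <- t(signal + noise)
  rownames(feat) <- paste0("f", seq_len(nf))
  ev <- env_variance_explained(feat, env)
  expect_gt(ev$fraction, 0.4)
  expect_lt(ev$fraction, 0.6)
})
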