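#' Principal component analysis of a z-score table
#'
#' Eigen-decomposition (via SVD) of the centred matrix under the
#' duality-diagram inertia convention: eigenvalues are the variances
#' of the projected coordinates with uniform row weights `1/n`. In
#' sample mode the samples are the observations (community
#' composition per sample); in feature mode the features are the
#' observations (similarity of temporal dynamics across genes or
#' taxa).
#'
#' @param tbl a z-score table (features x samples)
#' @param mode `"samples"` or `"features"`
#' @param n_axes number of axes to keep (default all)
#' @return object of class `ms_pca`: `scores` (tibble, one row per
#'   observation), `loadings` (tibble, one row per variable),
#'   `eigenvalues`, `variance_fraction`, `mode`
#' @export
pca_table <- function(tbl, mode = c("samples", "features"),
                      n_axes = NULL) {
  mode <- match.arg(mode)
  m <- if (is.matrix(tbl)) tbl else coverage_matrix(tbl)
  X <- if (mode == "samples") t(m) else m
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 rows and columns")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  eig <- sv$d^2 / nrow(X)
  k <- min(if (is.null(n_axes)) length(eig) else n_axes,
           sum(sv$d > max(sv$d) * 1e-12))
  load <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| element positive per axis
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- Xc %*% load
  axis <- sprintf("PC%d", seq_len(k))
  colnames(scores) <- colnames(load) <- axis
  structure(list(
    scores = tibble::tibble(id = rownames(X),
                            !!!tibble::as_tibble(scores)),
    loadings = tibble::tibble(id = colnames(X),
                              !!!tibble::as_tibble(load)),
    eigenvalues = eig[seq_len(k)],
    variance_fraction = (eig / sum(eig))[seq_len(k)],
    mode = mode
  ), class = "ms_pca")
}

#' @export
print.ms_pca <- function(x, ...) {
  cat("<ms_pca> mode:", x$mode, "\n  variance fractions:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_fraction, 5)),
            collapse = " "), "\n")
  invisible(x)
}

#' Multi-table co-inertia analysis
#'
#' Joint ordination of K feature tables sharing the same samples.
#' Axis h finds the synthetic sample-score direction `v` (unit norm
#' under the uniform row-weight metric `1/n`) maximising the summed
#' squared covariances with one best unit-norm loading direction in
#' each table; this is the eigen-decomposition of
#' `sum_k X_k X_k^T / n`. Each table is first rescaled to total
#' inertia 1 (by default) so no single annotation system dominates.
#' With K = 1 the analysis reduces exactly to PCA.
#'
#' @param tables named list of z-score tables (features x samples) or
#'   matrices, identical sample columns in identical order
#' @param n_axes axes to keep
#' @param scale_tables rescale each table to total inertia 1 first
#' @return object of class `ms_mcoa`: `scores` (synthetic sample
#'   scores, scaled so K = 1 matches PCA scores), `pseudo_eig`,
#'   `variance_fraction`, `table_loadings` (per-table unit loading
#'   vectors), `table_cov2` (per-table squared covariance per axis,
#'   summing to the pseudo-eigenvalue), `table_weights`
#' @export
mcoa <- function(tables, n_axes = 5, scale_tables = TRUE) {
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables))) names(tables) <- paste0("table", seq_along(tables))
  Xs <- lapply(tables, function(tb) {
    m <- if (is.matrix(tb)) tb else coverage_matrix(tb)
    t(m)                                       # samples x features
  })
  smp <- rownames(Xs[[1]])
  for (k in seq_along(Xs)) {
    if (!identical(rownames(Xs[[k]]), smp)) {
      stop("tables must share identical sample ordering")
    }
  }
  n <- nrow(Xs[[1]])
  Xs <- lapply(Xs, function(X) sweep(X, 2, colMeans(X)))
  inertia <- vapply(Xs, function(X) sum(X^2) / n, numeric(1))
  if (any(inertia <= 0)) stop("table with zero total variance")
  w <- if (scale_tables) 1 / inertia else rep(1, length(Xs))
  W <- Reduce(`+`, Map(function(X, wk) wk * tcrossprod(X), Xs, w))
  ee <- eigen(W / n, symmetric = TRUE)
  k <- min(n_axes, sum(ee$values > max(ee$values) * 1e-12))
  lambda <- ee$values[seq_len(k)]
  V <- ee$vectors[, seq_len(k), drop = FALSE] * sqrt(n)
  # sign anchored on the first table's loadings, matching pca_table()
  U1 <- crossprod(Xs[[1]], V)
  for (j in seq_len(k)) {
    i <- which.max(abs(U1[, j]))
    if (U1[i, j] < 0) V[, j] <- -V[, j]
  }
  loadings <- lapply(seq_along(Xs), function(kk) {
    U <- crossprod(Xs[[kk]], V) / n            # features x axes
    nrm <- sqrt(colSums(U^2))
    sweep(U, 2, pmax(nrm, 1e-300), "/")
  })
  cov2 <- vapply(seq_along(Xs), function(kk) {
    U <- loadings[[kk]]
    vapply(seq_len(k), function(j) {
      w[kk] * (sum(V[, j] * (Xs[[kk]] %*% U[, j])) / n)^2
    }, numeric(1))
  }, numeric(k))
  cov2 <- matrix(cov2, nrow = k,
                 dimnames = list(NULL, names(tables)))
  axis <- sprintf("Axis%d", seq_len(k))
  scores <- sweep(V, 2, sqrt(lambda), "*")
  colnames(scores) <- axis
  names(loadings) <- names(tables)
  structure(list(
    scores = tibble::tibble(sample = smp, !!!tibble::as_tibble(scores)),
    pseudo_eig = lambda,
    variance_fraction = lambda / sum(ee$values[ee$values > 0]),
    table_loadings = lapply(loadings, function(U) {
      colnames(U) <- axis
      tibble::as_tibble(U, rownames = "feature_id")
    }),
    table_cov2 = cov2, table_weights = w, n_samples = n
  ), class = "ms_mcoa")
}

#' @export
print.ms_mcoa <- function(x, ...) {
  cat("<ms_mcoa>", length(x$table_weights), "tables,",
      x$n_samples, "samples\n  shared-variance fractions:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_fraction, 5)),
            collapse = " "), "\n")
  invisible(x)
}

#' Distance-based PERMANOVA with sequential sums of squares
#'
#' Partitions the total sum of squares of a sample distance matrix
#' among categorical factors. The distance matrix is Gower-centred
#' (`G = -1/2 J D^2 J`); sequential (Type I) sums of squares come
#' from cumulative projection (hat) matrices of the factor design;
#' significance is by free permutation of sample identities, the same
#' permutation applied to every factor.
#'
#' @param x a `dist`, a symmetric distance matrix, or a z-score table
#'   (in which case Euclidean distance between samples is used)
#' @param data data frame of per-sample factors, rows ordered as the
#'   samples
#' @param terms character vector of terms in sequential order, e.g.
#'   `c("month", "year", "month:year")`
#' @param n_perm number of permutations
#' @param seed RNG seed for the permutations
#' @param perm_matrix optional integer matrix, one permutation of
#'   `1:n` per row, used instead of random draws (e.g. the exhaustive
#'   enumeration for small n); overrides `n_perm`
#' @return tibble of class `ms_permanova`: one row per term plus
#'   `Residual` and `Total`, with `df`, `ss`, `r_squared`,
#'   `pseudo_f`, `p_value`
#' @export
permanova <- function(x, data, terms = c("month", "year", "month:year"),
                      n_perm = 999, seed = 42, perm_matrix = NULL) {
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             isTRUE(all.equal(x, t(x), tolerance = 1e-8))) {
    D <- x
  } else {
    m <- if (is.matrix(x)) x else coverage_matrix(x)
    D <- as.matrix(stats::dist(t(m)))
  }
  n <- nrow(D)
  stopifnot(nrow(data) == n, all(abs(diag(D)) < 1e-12))
  A <- -0.5 * D^2
  # double-centred Gower matrix: A - row means - col means + grand mean
  G <- sweep(A, 1, rowMeans(A))
  G <- sweep(G, 2, colMeans(G))

  fdat <- as.data.frame(lapply(data, function(v) {
    droplevels(as.factor(v))
  }))
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(form, fdat)
  assign <- attr(X, "assign")

  # cumulative orthonormal bases -> per-term projection increments
  kept <- character(0)
  Hprev <- matrix(1 / n, n, n)                # intercept projection
  rank_prev <- 1L
  Hdiff <- list(); dfs <- integer(0)
  for (j in seq_along(terms)) {
    Xj <- X[, assign <= j, drop = FALSE]
    qrj <- qr(Xj)
    Qj <- qr.Q(qrj)[, seq_len(qrj$rank), drop = FALSE]
    Hj <- tcrossprod(Qj)
    df_j <- qrj$rank - rank_prev
    if (df_j == 0L) {
      warning("term '", terms[j],
              "' adds no estimable df (empty cells); dropped")
      next
    }
    Hdiff[[terms[j]]] <- Hj - Hprev
    dfs <- c(dfs, df_j)
    kept <- c(kept, terms[j])
    Hprev <- Hj; rank_prev <- qrj$rank
  }
  names(dfs) <- kept
  df_res <- n - rank_prev
  ss_total <- sum(diag(G))
  ss_terms <- vapply(Hdiff, function(H) sum(H * G), numeric(1))
  ss_res <- ss_total - sum(ss_terms)
  f_obs <- (ss_terms / dfs) / (ss_res / df_res)

  if (!is.null(perm_matrix)) {
    stopifnot(ncol(perm_matrix) == n)
    n_perm <- nrow(perm_matrix)
  }
  exceed <- rep(0, length(kept))
  if (n_perm > 0) {
    with_preserved_seed(seed, {
      for (b in seq_len(n_perm)) {
        p <- if (is.null(perm_matrix)) sample.int(n) else perm_matrix[b, ]
        Gp <- G[p, p]
        ss_p <- vapply(Hdiff, function(H) sum(H * Gp), numeric(1))
        ss_res_p <- ss_total - sum(ss_p)
        f_p <- (ss_p / dfs) / (ss_res_p / df_res)
        exceed <- exceed + (f_p >= f_obs - 1e-12)
      }
    })
  }
  pval <- if (n_perm > 0) (1 + exceed) / (1 + n_perm) else rep(NA_real_,
                                                               length(kept))
  out <- tibble::tibble(
    term = c(kept, "Residual", "Total"),
    df = unname(c(dfs, df_res, n - 1)),
    ss = unname(c(ss_terms, ss_res, ss_total)),
    r_squared = unname(c(ss_terms, ss_res, ss_total) / ss_total),
    pseudo_f = unname(c(f_obs, NA, NA)),
    p_value = unname(c(pval, NA, NA))
  )
  structure(out, class = c("ms_permanova", class(out)),
            n_perm = n_perm, seed = seed)
}
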