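# Independent oracles used across tests. Each re-derives a quantity
# from first principles (enumeration, normal equations, rank formulas)
# without touching the implementation path it checks.

# brute-force consensus taxonomy: tally every taxon at every rank,
# pick the deepest rank where some taxon reaches the threshold;
# tie-break parent-consistent then lexicographic (same declared rule,
# independent code path)
oracle_consensus <- function(lineages, threshold = 0.5) {
  ranks <- as.matrix(parse_lineage(lineages))
  n <- nrow(ranks)
  cons <- rep("unclassified", 7)
  for (r in 1:7) {
    vals <- ranks[, r]
    cand <- character(0)
    for (t in sort(unique(vals[vals != "unclassified"]))) {
      if (sum(vals == t) / n >= threshold) cand <- c(cand, t)
    }
    if (!length(cand)) break
    if (length(cand) > 1 && r > 1) {
      keep <- cand[vapply(cand, function(t) {
        any(vals == t & ranks[, r - 1] == cons[r - 1])
      }, logical(1))]
      if (length(keep)) cand <- keep
    }
    cons[r] <- sort(cand)[1]
  }
  cons
}

# pseudo-inverse OLS solve of the month+year sum-to-zero model
oracle_anomaly_ols <- function(y, month, year) {
  mf <- factor(month, levels = sort(unique(month)))
  yf <- factor(year, levels = sort(unique(year)))
  Xm <- stats::contr.sum(nlevels(mf))[as.integer(mf), , drop = FALSE]
  Xy <- stats::contr.sum(nlevels(yf))[as.integer(yf), , drop = FALSE]
  X <- cbind(1, Xm, Xy)
  beta <- drop(MASS::ginv(X) %*% y)
  km <- nlevels(mf)
  monthly <- stats::contr.sum(km) %*% beta[1 + seq_len(km - 1)]
  yearly <- stats::contr.sum(nlevels(yf)) %*%
    beta[km + seq_len(nlevels(yf) - 1)]
  list(intercept = beta[1], monthly = unname(drop(monthly)),
       yearly = unname(drop(yearly)),
       months = as.integer(levels(mf)), years = as.integer(levels(yf)))
}

# one-factor PERMANOVA pseudo-F from the classic distance formula:
# within-group SS from pairwise squared distances, no Gower matrix
oracle_permanova_f <- function(D, groups) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    ss_within <- ss_within + sum(D2[i, i][upper.tri(D2[i, i])]) / length(i)
  }
  ss_between <- ss_total - ss_within
  a <- length(unique(groups))
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# definitional Spearman: Pearson correlation of average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# all permutations of 1:n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# small simulator fixture shared by several tests
small_sim <- function(seed = 11, ...) {
  sim_config(n_taxa = 8,
             start_date = "2011-01-05", end_date = "2014-12-30",
             sampling_interval_days = 15, seed = seed, ...)
}

# random GTDB-style lineage strings over a small taxon pool
random_lineage_pool <- function(n_fam = 6) {
  sprintf("d__Bacteria;p__P%1$d;c__C%1$d;o__O%1$d;f__F%1$d;g__G%1$d;s__S%1$d",
          seq_len(n_fam))
}
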