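#' Simulation configuration for a synthetic coastal microbial community
#'
#' Builds the parameter set for the synthetic time-series generator.
#' Defaults emulate an ~11-year coastal ocean series sampled every 15
#' days (~268 samples): half the taxa are copiotroph-like (winter to
#' spring bloom peak, 3--6 Mbp genomes, iron-stress and
#' carbohydrate-degradation genes, negatively ENSO-sensitive) and half
#' oligotroph-like (summer to fall peak, 1--2.5 Mbp streamlined
#' genomes, N/P-stress genes, positively ENSO-sensitive). The default
#' ENSO index mimics the 2011--2021 ONI pattern: La Nina 2011--2013
#' and 2020--2021, strong El Nino 2015, weaker 2018--2019.
#'
#' @param n_taxa number of taxa (each one family-level lineage)
#' @param start_date,end_date calendar limits of the series
#' @param sampling_interval_days days between samples
#' @param seasonal_amplitude per-taxon amplitude of the cosine
#'   seasonal term on the latent log-abundance scale; recycled
#' @param seasonal_peak_month per-taxon peak month (1--12); recycled
#' @param enso_series ONI-like index, one value per calendar year in
#'   the date range (named by year or in year order)
#' @param enso_sensitivity per-taxon signed loading on `enso_series`
#' @param genome_size per-taxon genome size in base pairs
#' @param genes_per_taxon named list: taxon id -> character vector of
#'   gene-family IDs carried (KO/Pfam/COG/TIGRfam mixed)
#' @param total_reads reads drawn per sample
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 means
#'   plain multinomial sampling
#' @param noise_sd,noise_rho sd and AR(1) autocorrelation of the
#'   latent log-abundance noise
#' @param enso_scale degrees C of temperature anomaly per ONI unit
#' @param seed integer seed fixing every random draw
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_taxa = 40,
                       start_date = as.Date("2011-01-07"),
                       end_date = as.Date("2021-12-31"),
                       sampling_interval_days = 15,
                       seasonal_amplitude = NULL,
                       seasonal_peak_month = NULL,
                       enso_series = NULL,
                       enso_sensitivity = NULL,
                       genome_size = NULL,
                       genes_per_taxon = NULL,
                       total_reads = 1e6,
                       overdispersion = 0,
                       noise_sd = 0.3,
                       noise_rho = 0.9,
                       enso_scale = 1.5,
                       seed = 1L) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  stopifnot(n_taxa >= 1, total_reads > 0, overdispersion >= 0,
            sampling_interval_days > 0, noise_sd >= 0,
            noise_rho > -1, noise_rho < 1, end_date > start_date)
  dates <- seq(start_date, end_date, by = sampling_interval_days)
  years <- sort(unique(as.integer(format(dates, "%Y"))))

  taxon_id <- sprintf("Family_%02d", seq_len(n_taxa))
  guild <- rep(c("copiotroph", "oligotroph"), length.out = n_taxa)

  # per-taxon defaults are drawn once here so the truth is part of the
  # config, reproducible from `seed` alone
  drawn <- with_preserved_seed(seed, {
    list(
      amplitude = stats::runif(n_taxa, 0.6, 1.6),
      peak = ifelse(guild == "copiotroph",
                    sample(2:5, n_taxa, replace = TRUE),
                    sample(7:10, n_taxa, replace = TRUE)),
      sens = ifelse(guild == "copiotroph",
                    -abs(stats::rnorm(n_taxa, 0.5, 0.15)),
                    abs(stats::rnorm(n_taxa, 0.5, 0.15))),
      gsize = ifelse(guild == "copiotroph",
                     stats::runif(n_taxa, 3e6, 6e6),
                     stats::runif(n_taxa, 1e6, 2.5e6)),
      baseline = stats::rnorm(n_taxa, 0, 1)
    )
  })

  if (is.null(seasonal_amplitude)) seasonal_amplitude <- drawn$amplitude
  if (is.null(seasonal_peak_month)) seasonal_peak_month <- drawn$peak
  if (is.null(enso_sensitivity)) enso_sensitivity <- drawn$sens
  if (is.null(genome_size)) genome_size <- drawn$gsize
  seasonal_amplitude <- rep_len(seasonal_amplitude, n_taxa)
  seasonal_peak_month <- rep_len(as.integer(seasonal_peak_month), n_taxa)
  enso_sensitivity <- rep_len(enso_sensitivity, n_taxa)
  genome_size <- rep_len(genome_size, n_taxa)

  if (is.null(enso_series)) {
    oni_2011_2021 <- c(-1.0, -0.7, -0.3, 0.5, 2.0, 0.3, -0.1, 0.9,
                       0.6, -1.2, -0.9)
    enso_series <- rep_len(oni_2011_2021, length(years))
  }
  enso_series <- rep_len(enso_series, length(years))
  names(enso_series) <- years

  if (is.null(genes_per_taxon)) {
    genes_per_taxon <- default_gene_assignment(taxon_id, guild, seed)
  }
  stopifnot(all(seasonal_peak_month %in% 1:12), all(genome_size > 0))

  structure(list(
    n_taxa = n_taxa, taxon_id = taxon_id, guild = guild,
    lineage = default_lineages(taxon_id, guild),
    dates = dates, years = years,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_peak_month = seasonal_peak_month,
    enso_series = enso_series, enso_sensitivity = enso_sensitivity,
    genome_size = genome_size, genes_per_taxon = genes_per_taxon,
    baseline = drawn$baseline,
    total_reads = total_reads, overdispersion = overdispersion,
    noise_sd = noise_sd, noise_rho = noise_rho,
    enso_scale = enso_scale, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_taxa, " taxa, ", length(x$dates),
      " samples (", format(min(x$dates)), " to ", format(max(x$dates)),
      " every ", as.numeric(diff(x$dates[1:2])), " d), seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# run code under a seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# GTDB-style 7-rank lineage strings; one family per taxon
default_lineages <- function(taxon_id, guild) {
  n <- length(taxon_id)
  phylum <- ifelse(guild == "copiotroph",
                   rep_len(c("Bacteroidota", "Proteobacteria"), n),
                   rep_len(c("Proteobacteria", "Cyanobacteria"), n))
  sprintf("d__Bacteria;p__%s;c__%s_c;o__%s_o;f__%s;g__%s_g;s__%s_s",
          phylum, phylum, taxon_id, taxon_id, taxon_id, taxon_id)
}

#' Gene-family IDs of the 139 universal single-copy markers
#' @return character vector, length 139
#' @export
marker_gene_ids <- function() sprintf("marker_%03d", 1:139)

# default gene complement: shared core KOs, guild trait genes, random
# accessory genes per annotation system, and all 139 markers
default_gene_assignment <- function(taxon_id, guild, seed) {
  n <- length(taxon_id)
  core_ko <- sprintf("K%05d", 1:30)
  acc_ko <- sprintf("K%05d", 101:260)
  acc_pf <- sprintf("PF%05d", 1:120)
  acc_cog <- sprintf("COG%04d", 1:100)
  acc_tigr <- sprintf("TIGR%05d", 1:100)
  traits <- default_trait_gene_sets()
  with_preserved_seed(seed + 7L, {
    out <- lapply(seq_len(n), function(i) {
      g <- c(core_ko,
             sample(acc_ko, 40), sample(acc_pf, 30),
             sample(acc_cog, 25), sample(acc_tigr, 25),
             marker_gene_ids())
      if (guild[i] == "copiotroph") {
        g <- c(g, traits$Fe_stress, traits$C_degradation)
      } else {
        g <- c(g, traits$N_stress, traits$P_stress)
      }
      unique(g)
    })
    names(out) <- taxon_id
    out
  })
}

# gene IDs mirrored in inst/extdata/traits.yaml
default_trait_gene_sets <- function() {
  list(
    Fe_stress = c("K02012", "K02016", "K23227", "K02014"),
    N_stress = c("K01428", "K11959", "K15576", "K00370"),
    P_stress = c("K01113", "K02040", "K02044", "K05781"),
    C_degradation = c("PF00704", "PF01373", "PF02156", "PF00722")
  )
}

#' Simulate environmental covariates
#'
#' Temperature follows an annual sinusoid peaking in late summer plus
#' an ENSO anomaly (`enso_scale` degrees per ONI unit) and Gaussian
#' noise; nitrate and phosphate oscillate in anti-phase with
#' temperature (nutrient drawdown in the warm season); chlorophyll and
#' POC peak with the spring bloom. The ONI column repeats the yearly
#' index at every sample date.
#'
#' @param config a [sim_config()]
#' @param noise_sd measurement noise sd applied to each variable (on
#'   its own scale, scaled by each variable's amplitude)
#' @return tibble with date, month, year, temperature, nitrate,
#'   phosphate, chlorophyll, poc, cn, cp, np, oni
#' @export
simulate_environment <- function(config, noise_sd = 0.15) {
  stopifnot(inherits(config, "sim_config"))
  dates <- config$dates
  if (as.numeric(max(dates) - min(dates)) < 365) {
    stop("date range must span at least one year for a seasonal cycle")
  }
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  month <- as.integer(format(dates, "%m"))
  oni <- unname(config$enso_series[as.character(yr)])
  # phase anchored on day-of-year so the cycle is exactly annual
  seas <- function(peak_doy) cos(2 * pi * (doy - peak_doy) / 365.25)
  with_preserved_seed(config$seed + 11L, {
    nz <- function(amp) stats::rnorm(length(dates), 0, noise_sd * amp)
    temperature <- 17 + 4 * seas(227) + config$enso_scale * oni + nz(4)
    nitrate <- pmax(0.05, 2.5 - 2.0 * seas(227) - 0.6 * oni + nz(2))
    phosphate <- pmax(0.01, 0.25 - 0.15 * seas(227) - 0.04 * oni + nz(0.15))
    chlorophyll <- pmax(0.05, 1.2 + 0.9 * seas(105) + nz(0.9))
    poc <- pmax(1, 12 + 6 * seas(105) + nz(6))
    cn <- 6.6 + 0.8 * seas(227) + nz(0.8)
    cp <- 106 + 20 * seas(227) + nz(20)
    tibble::tibble(
      date = dates, month = month, year = yr,
      temperature = temperature, nitrate = nitrate,
      phosphate = phosphate, chlorophyll = chlorophyll, poc = poc,
      cn = cn, cp = cp, np = cp / cn, oni = oni
    )
  })
}

#' Simulate community coverage tables with known truth
#'
#' Latent log-abundance per taxon is
#' `baseline + amplitude * cos(2*pi*(month - peak_month)/12) +
#' enso_sensitivity * enso[year] + AR(1) noise`; relative abundances
#' are the per-sample softmax across taxa; read counts are multinomial
#' (Dirichlet-multinomial when `overdispersion > 0`); gene-family
#' coverage sums the coverage of the taxa carrying each gene.
#'
#' @param config a [sim_config()]
#' @param systems annotation systems to tabulate ("KO", "Pfam", "COG",
#'   "TIGRfam"); the family-level taxon table is always produced
#' @return list of class `community_sim`: `dates` (tibble with date,
#'   month, year), `taxa` (family coverage table), `genes` (named list
#'   of gene coverage tables per system), and `truth` (latent matrix,
#'   relative abundances, per-taxon true monthly/yearly anomaly
#'   vectors, noiseless expected gene proportions, per-sample true
#'   community average genome size)
#' @export
simulate_community <- function(config,
                               systems = c("KO", "Pfam", "COG", "TIGRfam")) {
  stopifnot(inherits(config, "sim_config"))
  dates <- config$dates
  n <- length(dates); p <- config$n_taxa
  month <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  enso_t <- unname(config$enso_series[as.character(yr)])

  seas_mat <- vapply(seq_len(p), function(i) {
    config$seasonal_amplitude[i] *
      cos(2 * pi * (month - config$seasonal_peak_month[i]) / 12)
  }, numeric(n))                                  # n x p
  det_latent <- t(seas_mat) + config$baseline +
    outer(config$enso_sensitivity, enso_t)        # p x n

  out <- with_preserved_seed(config$seed + 23L, {
    eps <- matrix(0, p, n)
    if (config$noise_sd > 0) {
      rho <- config$noise_rho
      innov_sd <- config$noise_sd * sqrt(1 - rho^2)
      eps[, 1] <- stats::rnorm(p, 0, config$noise_sd)
      for (t in 2:n) {
        eps[, t] <- rho * eps[, t - 1] + stats::rnorm(p, 0, innov_sd)
      }
    }
    latent <- det_latent + eps
    rel <- softmax_cols(latent)
    reads <- matrix(0, p, n)
    for (t in seq_len(n)) {
      pr <- rel[, t]
      if (config$overdispersion > 0) {
        a <- pr / config$overdispersion
        g <- stats::rgamma(p, shape = a, rate = 1)
        pr <- g / sum(g)
      }
      reads[, t] <- stats::rmultinom(1, config$total_reads, pr)
    }
    list(latent = latent, rel = rel, reads = reads)
  })

  sample_id <- format(dates, "S%Y%m%d")
  dimnames(out$reads) <- list(config$taxon_id, sample_id)
  taxa_tbl <- as_coverage_table(out$reads, system = "family",
                                lineage = config$lineage)

  empty <- vapply(config$genes_per_taxon[config$taxon_id], length,
                  1L) == 0
  if (any(empty)) {
    warning("taxa with empty gene sets contribute only to the taxon ",
            "table: ", paste(config$taxon_id[empty], collapse = ", "))
  }
  gene_tables <- lapply(stats::setNames(systems, systems), function(sys) {
    memb <- gene_membership(config, sys)
    if (nrow(memb) == 0) return(NULL)
    cov <- memb %*% out$reads
    dimnames(cov) <- list(rownames(memb), sample_id)
    as_coverage_table(cov, system = sys)
  })

  # truth on the latent scale: the injected seasonal/interannual terms,
  # centred so they are sum-to-zero anomaly vectors
  true_month <- vapply(1:12, function(m) {
    config$seasonal_amplitude *
      cos(2 * pi * (m - config$seasonal_peak_month) / 12)
  }, numeric(p))
  if (p == 1) true_month <- matrix(true_month, nrow = 1)
  true_month <- true_month - rowMeans(true_month)
  true_year <- outer(config$enso_sensitivity,
                     config$enso_series - mean(config$enso_series))
  colnames(true_year) <- names(config$enso_series)
  rownames(true_month) <- rownames(true_year) <- config$taxon_id

  det_rel <- softmax_cols(det_latent)
  dimnames(det_rel) <- dimnames(out$rel) <- list(config$taxon_id, sample_id)
  ags_true <- colSums(out$rel * config$genome_size)

  structure(list(
    dates = tibble::tibble(sample = sample_id, date = dates,
                           month = month, year = yr),
    taxa = taxa_tbl, genes = gene_tables,
    truth = list(latent = out$latent, rel_abund = out$rel,
                 expected_rel = det_rel,
                 monthly_effects = true_month,
                 yearly_effects = true_year,
                 peak_month = config$seasonal_peak_month,
                 genome_size = stats::setNames(config$genome_size,
                                               config$taxon_id),
                 guild = stats::setNames(config$guild, config$taxon_id),
                 ags = ags_true)
  ), class = "community_sim")
}

# column-wise softmax, shape-stable for a single row
softmax_cols <- function(M) {
  E <- exp(sweep(M, 2, apply(M, 2, max)))
  sweep(E, 2, colSums(E), "/")
}

# 0/1 gene-by-taxon membership matrix for one annotation system
gene_membership <- function(config, system) {
  pref <- c(KO = "^K\\d", Pfam = "^PF\\d", COG = "^COG\\d",
            TIGRfam = "^TIGR\\d")[[system]]
  sets <- lapply(config$genes_per_taxon[config$taxon_id],
                 function(g) grep(pref, g, value = TRUE))
  genes <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(g) as.numeric(genes %in% g),
                 numeric(length(genes)))
  if (length(genes) == 1) memb <- matrix(memb, nrow = 1)
  rownames(memb) <- genes
  memb
}

#' Simulate contigs with ORF-level lineage assignments
#'
#' Each contig originates from one source taxon (sampled by mean
#' relative abundance); each of its ORFs carries the source lineage
#' with probability `1 - misassignment_rate` and otherwise a random
#' other taxon's lineage. Contig coverage is proportional to the
#' source taxon's coverage.
#'
#' @param config a [sim_config()]
#' @param n_contigs number of contigs
#' @param orfs_per_contig ORFs per contig
#' @param misassignment_rate per-ORF probability of a wrong lineage,
#'   in `[0, 0.5)`
#' @param community optional pre-computed [simulate_community()] result
#' @return list: `orfs` (tibble contig_id, orf_id, coverage, lineage,
#'   ko, pfam), `sample_coverage` (coverage table, features = contigs),
#'   `truth` (tibble contig_id, source_taxon, lineage)
#' @export
simulate_contigs <- function(config, n_contigs = 500,
                             orfs_per_contig = 10,
                             misassignment_rate = 0,
                             community = NULL) {
  stopifnot(inherits(config, "sim_config"),
            misassignment_rate >= 0, misassignment_rate < 0.5)
  if (is.null(community)) community <- simulate_community(config,
                                                          systems = "KO")
  rel <- community$truth$rel_abund
  mean_rel <- rowMeans(rel)
  p <- config$n_taxa
  with_preserved_seed(config$seed + 31L, {
    src <- sample.int(p, n_contigs, replace = TRUE, prob = mean_rel)
    size_factor <- stats::rlnorm(n_contigs, 0, 0.3)
    cov_mat <- rel[src, , drop = FALSE] * size_factor * 100
    contig_id <- sprintf("contig_%04d", seq_len(n_contigs))
    rownames(cov_mat) <- contig_id

    n_orf <- n_contigs * orfs_per_contig
    orf_src <- rep(src, each = orfs_per_contig)
    wrong <- stats::runif(n_orf) < misassignment_rate
    if (any(wrong) && p > 1) {
      # a random OTHER taxon, never the source
      alt <- vapply(orf_src[wrong], function(s) {
        sample(seq_len(p)[-s], 1)
      }, 1L)
      orf_src[wrong] <- alt
    }
    kos <- vapply(config$genes_per_taxon[orf_src], function(g) {
      k <- grep("^K\\d", g, value = TRUE)
      if (length(k)) sample(k, 1) else NA_character_
    }, character(1))
    pfs <- vapply(config$genes_per_taxon[orf_src], function(g) {
      k <- grep("^PF\\d", g, value = TRUE)
      if (length(k)) sample(k, 1) else NA_character_
    }, character(1))
    orf_contig <- rep(contig_id, each = orfs_per_contig)
    orfs <- tibble::tibble(
      contig_id = orf_contig,
      orf_id = sprintf("%s_orf%02d", orf_contig,
                       rep(seq_len(orfs_per_contig), n_contigs)),
      coverage = rep(rowMeans(cov_mat), each = orfs_per_contig),
      lineage = config$lineage[orf_src],
      ko = kos, pfam = pfs
    )
    list(
      orfs = orfs,
      sample_coverage = as_coverage_table(cov_mat, system = "contig"),
      truth = tibble::tibble(contig_id = contig_id,
                             source_taxon = config$taxon_id[src],
                             lineage = config$lineage[src])
    )
  })
}

#' Simulate single-copy marker-gene counts and assembly sizes
#'
#' Every taxon carries each of the 139 universal markers exactly once,
#' so each marker's per-sample count equals the summed cell coverage
#' across taxa (optionally perturbed by log-normal per-marker noise);
#' total assembled bases per sample is coverage-weighted genome size.
#'
#' @param config a [sim_config()]
#' @param marker_ids marker gene-family IDs (default the 139 universal
#'   single-copy markers)
#' @param community optional pre-computed [simulate_community()] result
#' @param marker_noise_sd sd of log-normal noise on each marker count
#' @return list: `markers` (coverage table, 139 rows x samples),
#'   `total_bases` (tibble sample, bases), `truth` (tibble sample,
#'   ags = abundance-weighted mean genome size)
#' @export
simulate_marker_counts <- function(config, marker_ids = marker_gene_ids(),
                                   community = NULL,
                                   marker_noise_sd = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(community)) community <- simulate_community(config,
                                                          systems = "KO")
  cov <- coverage_matrix(community$taxa)
  total_cov <- colSums(cov)
  m <- length(marker_ids)
  counts <- matrix(rep(total_cov, each = m), nrow = m,
                   dimnames = list(marker_ids, colnames(cov)))
  if (marker_noise_sd > 0) {
    counts <- with_preserved_seed(config$seed + 41L, {
      counts * exp(matrix(stats::rnorm(length(counts), 0, marker_noise_sd),
                          nrow = m))
    })
  }
  bases <- colSums(cov * config$genome_size)
  list(
    markers = as_coverage_table(counts, system = "marker"),
    total_bases = tibble::tibble(sample = colnames(cov), bases = bases),
    truth = tibble::tibble(sample = colnames(cov),
                           ags = unname(colSums(community$truth$rel_abund *
                                                  config$genome_size)))
  )
}
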