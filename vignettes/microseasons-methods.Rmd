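---
title: "Methods: models, conventions and design choices in microseasons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in microseasons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microseasons)
```

`microseasons` quantifies seasonal and interannual succession in
multi-year metagenomic time series from a single monitoring site.
This vignette is the package's own account of the models it fits, the
numerical conventions it commits to, the design decisions that were
genuinely open, and what the synthetic-data tests do and do not
establish about real data.

## The anomaly model

Every feature series — a family's or gene family's z-scored relative
proportion, an environmental variable, a community-aggregated trait,
the average genome size — is decomposed by ordinary least squares on

$$y(t) = \mu + \alpha_{m(t)} + \beta_{y(t)} + \varepsilon(t),
\qquad \textstyle\sum_m \alpha_m = \sum_y \beta_y = 0,$$

where $m(t) \in \{1,\dots,12\}$ is the calendar month and $y(t)$ the
calendar year of sample $t$. The twelve $\alpha_m$ are the *seasonal
anomaly*, the per-year $\beta_y$ the *interannual anomaly*; no
interaction is fitted. Conventions:

* **Sum-to-zero (effects) coding**, so each effect is a deviation
  from the grand mean on the response's own scale — the quantity
  plotted in anomaly heatmaps. Levels with no observations are
  dropped with a warning and reported as `NA`.
* **Sequential (Type I) sums of squares, month entered first.** In
  these series the seasonal signal dominates, so the seasonal SS is
  charged first and the yearly SS is the increment; the order is an
  argument (`order`) for sensitivity checks. For balanced designs the
  partition is order-free; for unbalanced ones sequential SS still
  sum exactly to the total SS, which the tests assert.
* **No imputation.** Irregular sampling (gaps, uneven spacing) is
  handled by OLS on the observed design only.
* **Unbalanced-design estimation** is a single QR factorisation
  shared across all features of a table (`fit_anomaly_table()`), so a
  200-feature table costs one decomposition.
* **Scaling for presentation** divides effects by the maximum
  absolute effect, mapping to $[-1, 1]$; an all-zero vector is left
  untouched rather than divided by zero.
* **Peak ordering.** Features are ordered by the arg-max month of
  $\alpha$; ties are broken by the circular phase of a first-harmonic
  cosine fit, which is continuous where the arg-max is not.

`variance_fractions()` reports SS components over the total; a
constant series has no defined fractions and is an error rather than
a `NaN`.

### Interannual variance explained by the environment

`env_variance_explained()` regresses each feature's yearly-effect
vector on environmental yearly effects (e.g. temperature and nitrate)
and pools $\sum(\text{explained SS}) / \sum(\text{total SS})$ across
features — a redundancy-style statistic. How much interannual
microbiome variance is "tied to a linear combination" of environment
admits several readings (per-feature averaging, canonical analysis,
pooled regression); the pooled OLS reading implemented here is one
defensible choice and is flagged as such. With few years and an
intercept plus two covariates, per-feature $R^2$ carries an
overfitting inflation of roughly $p/(n_\text{years}-1)$; the recovery
test budgets for this rather than pretending it away.

## Normalisation

Coverage tables are normalised to per-sample relative proportions
(zero-total samples are an error naming the sample). Features whose
**mean** proportion across samples falls below $5\times10^{-5}$ are
excluded; the boundary is inclusive (exactly $5\times10^{-5}$ is
retained, since it is not *below* the threshold). The mean — rather
than an any-sample — criterion gives one fixed feature set across the
whole series, which downstream PCA/MCOA require. Dropped features are
kept in a provenance attribute.

Z-scoring standardises each feature to mean 0, sd 1 with the $n-1$
sample sd; at $n \approx 268$ the $n$ vs $n-1$ choice is immaterial,
but fixing it makes tests exact. Zero-variance features are excluded
with a warning. `zscore_table(log = TRUE)` log-transforms proportions
first (zeros replaced by half the smallest positive value): when
abundances follow a log-linear seasonal model — as the simulator's
latent process does — the log scale is where injected effects are
linear, and recovery against simulator truth is therefore measured
there. The plain-proportion path remains the default for data
analysis; the qualitative structure (peak months, orderings,
anti-phase patterns) is recovered on either scale and is tested on
the default path.

`robust_loess()` delegates to `stats::loess` with local linear
fitting, tricube weights and iterated bisquare robustness
(`family = "symmetric"`, 3 robustness iterations, exact `"direct"`
surface) — the standard robust lowess smoother. Default span 0.3 of
the series. (The `stats::lowess` implementation was rejected because
its robustness weights degenerate when the median residual is zero,
e.g. a single gross outlier on an otherwise constant series.)

## Consensus taxonomy

A contig's consensus lineage is the deepest rank at which some taxon
name is carried by at least a threshold fraction (default 0.5,
boundary inclusive: "at least 50%") of the contig's ORFs. Evaluation
proceeds domain→species and stops at the first rank where no taxon
reaches the threshold; lower ranks are `unclassified`. Two decisions
the rule itself does not settle:

* **ORFs unclassified at a rank stay in the denominator**, diluting
  support — "50% of open reading frames" is read as all ORFs, not
  classified-at-that-rank ORFs.
* **Exact ties at threshold** (possible only at exactly 50%) prefer
  the candidate consistent with the parent-rank consensus, then break
  lexicographically. Parent-consistency preserves the lineage prefix
  property; lexicographic order makes the result deterministic.

Abundance aggregation weights by **contig coverage**, not ORF count.
Contigs not resolved to family accumulate under
`"<rank>:<name>_unresolved"` so family tables remain
coverage-complete (column sums are preserved exactly). The
implementation is checked rank-for-rank against a brute-force tally
oracle on 1,000 random contigs at misassignment rates 0–0.4.

## Ordination

**PCA and MCOA share one inertia convention**: eigenvalues are
variances of projected coordinates under uniform row weights $1/n$
(the duality-diagram convention). MCOA axis $h$ maximises
$\sum_k w_k \,\mathrm{cov}^2(X_k u_k, v)$ over unit-norm per-table
loadings $u_k$ and a synthetic sample direction $v$ (unit norm in the
$1/n$ metric, orthogonal across axes), computed as the
eigen-decomposition of $\sum_k w_k X_k X_k^\top / n$. Reported
synthetic scores are $v\sqrt{\lambda_h}$ with the sign anchored on
the first table's largest loading, so $K=1$ reduces *exactly* to PCA
— eigenvalues and scores — which the tests assert at $10^{-8}$.

**Table weighting** was genuinely open: the behaviour of the original
multi-table analysis cannot be recovered from a methods paragraph.
Each table is first rescaled to total inertia 1 and then weighted
uniformly, so the largest annotation system (typically KO, with the
most gene families) cannot dominate the shared axes; the weights are
an argument (`scale_tables`) and are reported in the result.

**PERMANOVA** follows the standard distance-based formulation: Gower
double-centring $G = -\tfrac12 J D^2 J$, sequential SS via cumulative
projection matrices of the factor design, pseudo-$F$ per factor
against the residual, and significance by free permutation of sample
identities — the same permutation applied to every factor — with
$p = (1 + \#\{F^\pi \ge F\})/(1 + n_\text{perm})$. An 11-year
biweekly series cannot fill all 132 month×year cells; an interaction
(or any term) that adds no estimable df is dropped with a warning
rather than silently absorbing rank. The implementation is
cross-checked against `vegan::adonis2` (SS, $F$, $R^2$) and against
an exhaustive-enumeration oracle at $n=6$; its type-I error under an
iid Gaussian null is calibrated at $\alpha=0.05$ over 500 simulations.

## Traits, genome size, keywords

**Community-aggregated traits** sum member-gene coverage per sample
and divide by the *total annotated coverage of the table* — the
all-annotated denominator implied by expressing a trait as a share of
all annotated sequences — so disjoint traits add linearly and
splitting a gene's coverage across rows changes nothing. The shipped
`traits.yaml` (Fe/N/P stress, carbon degradation; transporter /
alternative-form / regulation roles per gene) is an editable,
deliberately small default sufficient for simulation work — a
synthetic stand-in, not a curated database reproduction. Interannual
trait–environment association uses Spearman correlation with average
ranks for ties; nitrate enters as *nitrate stress*, $-1 \times$
nitrate, so positive rho means "more of the trait in low-nitrate
years".

**Average genome size** is total assembled bases over the estimated
genome count, the latter the arithmetic **mean** of the 139 single-copy
marker counts (mean vs median was open; the mean is the documented
default and the tests pin it). Markers absent from a shallow assembly
count as zero, inflating the coefficient of variation and naturally
tripping the CV ≥ 50% unreliability flag, under which no AGS value is
reported. Per-marker "coverage-weighted counts" are defined by the
simulator contract: each taxon carries each marker once, so a
marker's count is the summed cell coverage.

**Keywords** are lowercased alphabetic tokens of length ≥ 3 with a
versioned stop-word list removed, counted at most once per gene
(binary occurrence, robust to verbose annotations). A keyword's
series is the summed relative proportion of its member genes.
Part-of-speech filtering (nouns/verbs only) is a documented optional
refinement; the deterministic token filter is the default so results
do not depend on a language-model download, and the tested contract
is the *ranking* by seasonal and annual variance fractions, not the
token inventory.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults encode the study conditions the analysis
assumes: ~15-day sampling over 2011–2021 (268 samples), 40 taxa in
two guilds — copiotroph-like (peak months 2–5, 3–6 Mbp genomes,
Fe-stress and CAZyme genes, negative ENSO sensitivity) and
oligotroph-like (peak months 7–10, 1–2.5 Mbp streamlined genomes,
N/P-stress genes, positive ENSO sensitivity) — an ONI-like yearly
index mimicking the 2011–2021 ENSO sequence, latent log-abundance
with cosine seasonality (the simplest model with "peak month"
semantics), AR(1) noise with $\rho = 0.9$ reflecting the strong
sample-to-sample autocorrelation of such series, and compositional
read sampling (multinomial; Dirichlet-multinomial when
`overdispersion > 0`) because metagenomic tables carry relative, not
absolute, abundance. All dates are reduced to (month, year) factors
at generation time so the simulator and the anomaly module share one
calendar convention, and a fixed seed fixes every emitted table
bit-for-bit.

Deliberate simplifications, hence limits on what passing tests show
about real data: read yield is proportional to cell abundance, not to
cell abundance × genome size; gene content is static within a taxon
(no gain/loss, no strain variation); ORF misassignment is uniform
across ranks rather than phylogenetically structured; environmental
series are parametric sinusoids plus noise; and there is no
sequencing-error or assembly model at all (the package consumes
already-annotated tables by design). Recovery results therefore
establish the *statistical machinery* — not that any particular
field dataset satisfies the generative assumptions.

## Problem sizes and numerical tolerances

The test and verification suite uses: 200 features × 268 samples for
study-scale anomaly recovery (amplitude/noise-sd = 2; fitted monthly
effects correlate $r \ge 0.95$ with truth for ≥ 95% of features);
500 null simulations × 199 permutations at $n=60$, $p=20$ for
PERMANOVA size; all $6! = 720$ permutations for the enumeration
check; 1,000 contigs × 20 ORFs for the consensus oracle; $10^6$
multinomial reads for AGS recovery (exact at zero noise, within 10%
sampled); 10,000 random directions for MCOA criterion maximality.
Algebraic identities are asserted at $10^{-8}$–$10^{-12}$; identities
involving an eigen- or QR-decomposition at $10^{-8}$; statistical
recovery bands follow the binomial or simulation noise of the check
itself. These sizes are the package's reference verification
conditions and are what `scripts/acceptance.R` re-runs end to end.

## Known limitations

* The month factor treats month boundaries as sharp; phenology that
  drifts across a boundary between years smears into the residual.
* Euclidean-on-z-scores ordination presumes the rare-feature filter
  has removed most zeros; with many zeros a compositional log-ratio
  treatment (out of scope here) would be preferable.
* `env_variance_explained()` is correlational; with ~11 yearly
  effects per feature its per-feature $R^2$ values are noisy and only
  the pooled fraction is reported as a headline quantity.
* The Spearman critical value used in the trait null-calibration test
  is the $n=11$ two-sided 5% point; with so few years, only strong
  interannual associations are detectable.
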