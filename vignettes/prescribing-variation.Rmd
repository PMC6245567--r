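---
title: "Models and methods behind rxscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rxscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rxscape` analyses provider prescribing-pattern variation in
privacy-censored claims data. This vignette explains the statistical
models and the design choices behind each stage, what the synthetic-data
generator does and does not emulate, and the package's known
limitations.

## The data model and the censoring rule

The input is the three-table public-use layout: a provider table keyed
by NPI, a drug table keyed by the (brand name, generic name) pair — a
single name is not unique, the pair is, and the package refuses a
single-name key — and a long provider–drug table of claim counts. The
`ClaimsExperiment` container holds the counts as a sparse drugs ×
providers matrix (features as rows, samples as columns, the
Bioconductor convention) with provider and drug annotations alongside.

Public releases censor small cells: a provider–drug count below the
threshold *t* (11 in the CMS release) is set to zero. Two phrasings of
the rule circulate — "less than 11" and "≤ 11". The package adopts the
strict form, `α < t → 0`, so a count exactly at the threshold survives;
this is consistent with how surviving providers and drugs are counted
("≥ 11 claims for at least one drug"). The threshold is configurable
and recorded on the object, and the class validity enforces that every
stored non-zero is at or above it. Censoring at a threshold is
idempotent, monotone, and composes (`t2 ≥ t1` after `t1` equals `t2`
alone); these algebraic facts are property-tested.

One consequence is worth stating plainly: compositions are computed on
*censored* counts, because only censored data exist downstream of a
public release. For low-volume providers the surviving cells
over-represent their concentrated drugs, a known bias that no
normalization can undo.

## Profiles and skew statistics

Per-provider feature vectors are built at the drug or the drug-class
level; class aggregation sums member-drug counts per provider *before*
any normalization, so totals are conserved exactly. Normalization
divides by the provider total, giving a composition on the simplex.

Skew is summarised by the Gini index with values sorted ascending:

$$G = \frac{\sum_{i=1}^{n}(2i-n-1)\,x_i}{n^2\mu}.$$

The denominator is exactly \(n^2\mu\), with no small-sample \(n(n-1)\)
correction — the plain rank-form of the statistic. Its equivalence to
the mean-absolute-difference form
\(G = \sum_{i,j}|x_i-x_j| / (2n^2\mu)\) is used as an independent test
oracle at tolerance 1e-12. The confidence interval is a percentile
bootstrap over observations, 1000 resamples by default; the resampling
scheme is the ordinary nonparametric bootstrap because nothing more
specific is standard for this statistic.

Cohort splits (high-volume vs standard-volume, default threshold 25,000
claims with the boundary provider counted high-volume) compare
specialty composition with a chi-square test on the contingency table —
the conventional choice for a composition difference when no test is
otherwise specified. State share fits are ordinary least squares of
provider share on enrollee share, both in percent.

## Embedding

Providers are first projected onto the top principal components
(default 50) of the centered composition matrix. No additional variance
scaling is applied: the only normalization is by provider totals, so
high-prevalence features legitimately carry more variance. If the
requested dimension exceeds the matrix rank, the rank number of
components is kept with a warning.

The two-dimensional embedding is t-SNE with the exact gradient:
Gaussian input affinities calibrated per point to a target perplexity
(default 40) by binary search on the Shannon entropy, symmetrized and
floored at 1e-12; a Student-t output kernel; early exaggeration (factor
12 for the first third of iterations, capped at 100); adaptive gains;
and momentum switching from 0.5 to 0.8. The exact \(O(n^2)\) gradient
is used because the cohorts this package embeds are thousands of points
at most, where approximation is unnecessary; the Barnes–Hut accuracy
parameter `theta` is accepted for interface compatibility but does not
change the exact computation. The optimisation restarts `n_restarts`
times (default 5) from seeds derived from the user seed, and the run
with the minimum final Kullback–Leibler divergence is returned — final
cost is always evaluated against the unexaggerated affinities. A fixed
seed gives bit-identical coordinates.

Annotation layers colour each provider by the percentage of claims for
one drug or class, clipped at a display cap (default 15%), so a handful
of extreme prescribers do not flatten the scale for everyone else.

## Clustering

Provider clustering is agglomerative with Ward's minimum-variance
criterion on Euclidean distances over the same composition matrix used
for the embedding (clustering validates the embedding's groupings, so
both see the same features). Centroid linkage is available behind a
flag. The cluster count is a required input — cut by count or by merge
height — and no automatic selection is claimed. Agreement with a naive
Lance–Williams agglomeration is verified exhaustively for small inputs.

Cluster–specialty dominance is the fraction of a cluster belonging to
its most frequent specialty (ties broken lexicographically and
flagged), summarised as the share of clusters whose dominant fraction
reaches a threshold (default 0.30).

## Regional analysis

Region profiles restrict features to those with national claims
*strictly greater* than a floor, sum claims per region, and divide by
Part D enrollee counts. Region dissimilarity is \(d_{ij} = 1 - r_{ij}\)
with \(r_{ij}\) the Pearson correlation of the two regions'
claims-per-enrollee vectors; classical (Torgerson) MDS embeds the
regions, truncating negative eigenvalues with a warning since \(1-r\)
distances need not be Euclidean.

The reference distribution for regional separation is a permutation
null: provider→region labels are shuffled preserving the exact number
of providers per region, and the whole profile → distance → MDS chain
is recomputed per permutation (default 100). Because MDS is defined
only up to rotation and translation, each permuted configuration is
Procrustes-aligned (no scaling) to the real one before comparison; the
summary statistic is the mean distance of region points from their
centroid, reported as the real configuration's percentile in the null.
Scaling is excluded from the alignment precisely because the null's
*smaller* dispersion is the signal being measured.

Pairwise region comparisons flag features whose claims-per-enrollee
ratio exceeds a fold band (default 5). Features with a zero rate in
either region are excluded by default — they cannot be placed on the
log-scale plot this comparison feeds — with a pseudocount option for
users who want them retained.

The prescribing-vs-prevalence analysis computes Euclidean distance
matrices between per-state mean prescribing vectors and per-state
disease-prevalence vectors and reports the squared Pearson correlation
of their upper triangles. The source analysis describes this value as
coming from an analysis of variance; the squared upper-triangle
correlation is the standard Mantel-style operationalisation of exactly
that quantity, and is what this package computes. It is invariant to
rescaling either domain.

The Mann–Whitney comparison of region fraction samples uses the exact
null distribution for combined samples up to 20 without ties and the
normal approximation with tie correction above, without continuity
correction so that the maximal-tie case returns p = 1 exactly.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Specialty profiles.** Each specialty's Dirichlet concentration is
  \(\tau m_s\) where \(m_s\) places 90% of mass on the specialty's own
  drug block with Zipf (1/rank) weights — all providers of a specialty
  share the same few workhorse drugs at provider-varying proportions —
  plus a uniform baseline over the formulary for the long sparse tail.
  The precision \(\tau = 30\) gives realistic provider-to-provider
  variability. No empirical per-specialty parameters exist to calibrate
  against, so these presets are illustrative, not calibrated.
* **Volumes.** Per-provider totals are log-normal (meanlog 6.2, sdlog
  1.3): median near 490 claims, heavy right tail with roughly 0.1–0.3%
  of providers above 25,000 claims — a two-parameter model reproducing
  the observed skew of real claim volumes.
* **Regions.** Regional effects are multiplicative per-drug factors
  applied to the profile before renormalization, log-normal with a
  configurable `effect_sd` (0 = exchangeable regions). This is the
  simplest mechanism that produces metropolitan-level profile
  divergence. Optionally the effects derive from latent per-region
  disease-prevalence vectors through a linear map plus noise.
* **Mixed practices.** A configurable fraction of providers (default
  5%) draw a 50/50 mixture of two specialty profiles; no empirical
  model of practice mixing exists, so the even mixture is the neutral
  choice.
* **Censoring.** Applied at the configured threshold (default 11) after
  the multinomial allocation, exactly as the public release does.
* **State profiles.** A separate generator produces per-state
  prescribing and disease-prevalence vectors either independently or
  linked by a similarity-type affine map (orthonormal rows, uniform
  scale, offset) plus noise, so inter-state prescribing distances are
  proportional to prevalence distances up to the noise — a clean
  tunable ground truth for the distance-correlation analysis.

What the generator does **not** emulate: beneficiary demographics,
costs and day-supply; provider social-network effects; formulary
restrictions; and the real data's specialty-specific diversity
distributions. Passing recovery tests therefore demonstrates that the
pipeline's machinery is correct and sensitive under planted structure,
not that any particular real-data finding would replicate.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so
the full chain exercises every code path in minutes: populations of
120–1000 providers over 40–150 drugs; t-SNE on up to 600 points with
300–500 iterations and 1–2 restarts; permutation nulls with 59–199
permutations. The headline statistics of the full national data set
(hundreds of thousands of providers) are not reproducible at these
sizes and are not asserted; what is asserted is exact worked-example
arithmetic, oracle equivalence (Gini vs mean absolute difference, Ward
vs naive agglomeration, MDS distance recovery, Mann–Whitney vs
enumeration), and planted-structure recovery at fixed seeds.

Degenerate inputs are handled explicitly: all-zero matrices warn and
return empty; zero-variance region rows are an error naming the region
(a correlation distance is undefined there); zero-total providers get a
flagged 0 in annotation layers; single-state share fits are flagged
degenerate rather than fit; empty cohorts skip the composition test
with a warning.

## Known limitations

* Compositions are post-censoring by necessity; low-volume providers'
  profiles are biased toward their concentrated drugs.
* The exact t-SNE gradient is quadratic in the number of points; the
  package targets cohort-scale embeddings, not the full national
  matrix.
* The drug-class count is emergent from the class map and censoring; no
  particular class count is forced or asserted.
* Cluster count selection is the user's: the package cuts where told
  and reports diagnostics, it does not choose k.
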