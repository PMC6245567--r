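## Region-level profile construction, correlation-distance MDS with a
## label-permutation null, pairwise fold comparisons, and the
## prescribing-distance vs disease-prevalence-distance correlation.

#' Per-provider region labels
#'
#' @param x a [ClaimsExperiment-class].
#' @param level `"cbsa"` or `"state"`.
#' @return named character vector (`NA` for providers outside any CBSA).
#' @export
providerRegions <- function(x, level = c("cbsa", "state")) {
  level <- match.arg(level)
  col <- if (level == "cbsa") "cbsa" else "nppes_provider_state"
  lab <- colData(x)[[col]]
  if (is.null(lab)) stop(sprintf("provider annotations lack '%s'", col), call. = FALSE)
  stats::setNames(as.character(lab), colnames(x))
}

#' Region-by-feature claims-per-enrollee profiles
#'
#' Restricts the claims matrix to features whose national claim total is
#' strictly greater than `min_national_claims`, sums claims per region,
#' and divides each region row by its Part D enrollee count. Providers
#' without a region label are excluded; regions without a (positive)
#' enrollee count are excluded with a warning.
#'
#' @param x a [ClaimsExperiment-class].
#' @param regions named per-provider region labels (see
#'   [providerRegions()]).
#' @param enrollees named per-region enrollee counts.
#' @param min_national_claims strict national-claims filter (the
#'   metropolitan analysis uses 100,000 on the full data; scale it to the
#'   population at hand).
#' @return a [RegionProfiles-class].
#' @export
regionProfiles <- function(x, regions, enrollees, min_national_claims = 0) {
  cnt <- claimCounts(x)
  regions <- regions[colnames(cnt)]
  keep_p <- !is.na(regions)
  cnt <- cnt[, keep_p, drop = FALSE]
  regions <- regions[keep_p]
  keep_f <- Matrix::rowSums(cnt) > min_national_claims
  if (!any(keep_f))
    stop(sprintf("no feature has national claims > %s", min_national_claims),
         call. = FALSE)
  cnt <- cnt[keep_f, , drop = FALSE]
  regs <- sort(unique(regions))
  missing_enr <- regs[!regs %in% names(enrollees) | enrollees[regs] <= 0 |
                        is.na(enrollees[regs])]
  if (length(missing_enr)) {
    warning(sprintf("region(s) without positive enrollee counts excluded: %s",
                    paste(missing_enr, collapse = ", ")))
    regs <- setdiff(regs, missing_enr)
  }
  ok <- !is.na(match(regions, regs))
  ind <- Matrix::sparseMatrix(i = match(regions[ok], regs), j = which(ok),
                              x = 1, dims = c(length(regs), length(regions)))
  sums <- as.matrix(ind %*% Matrix::t(cnt))   # regions x features
  dimnames(sums) <- list(regs, rownames(cnt))
  rates <- sums / as.numeric(enrollees[regs])
  new("RegionProfiles", rates = rates,
      enrollees = stats::setNames(as.numeric(enrollees[regs]), regs),
      minNationalClaims = as.numeric(min_national_claims))
}

#' One-minus-correlation distance between region profiles
#'
#' Distance between region rows \eqn{d_{i,j} = 1 - r_{i,j}}, with
#' \eqn{r_{i,j}} the Pearson product-moment correlation of the two
#' regions' claims-per-enrollee feature vectors; values lie in
#' `[0, 2]` with a zero diagonal.
#'
#' @param profiles a [RegionProfiles-class] or a plain regions-by-features
#'   matrix.
#' @return symmetric distance matrix with attribute `metric`.
#' @export
correlationDistance <- function(profiles) {
  m <- if (is(profiles, "RegionProfiles")) regionRates(profiles) else as.matrix(profiles)
  if (ncol(m) < 2)
    stop("at least 2 features are required for a correlation distance", call. = FALSE)
  v <- apply(m, 1, stats::var)
  if (any(v == 0))
    stop(sprintf("correlation undefined for zero-variance region(s): %s",
                 paste(rownames(m)[v == 0], collapse = ", ")), call. = FALSE)
  d <- 1 - stats::cor(t(m))
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  attr(d, "metric") <- "1 - Pearson r"
  d
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centered Gram eigendecomposition (Torgerson scaling) returning
#' the top-`k` coordinates. Negative eigenvalues (non-Euclidean part of
#' the distances) are truncated with a warning; if fewer than `k`
#' eigenvalues are positive, `k` is reduced with a warning.
#'
#' @param D symmetric distance matrix.
#' @param k embedding dimension (default 2).
#' @return coordinates matrix (regions x k) with attribute `eig`.
#' @export
classicalMds <- function(D, k = 2) {
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric", call. = FALSE)
  fit <- stats::cmdscale(stats::as.dist(D), k = min(k, nrow(D) - 1), eig = TRUE)
  ev <- fit$eig
  npos <- sum(ev > max(abs(ev)) * 1e-9)
  if (any(ev < -max(abs(ev)) * 1e-9))
    warning("negative eigenvalues truncated (distances are not exactly Euclidean)")
  pts <- fit$points
  if (npos < k) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d dimension(s)",
                    npos, npos))
    pts <- pts[, seq_len(max(1, npos)), drop = FALSE]
  }
  rownames(pts) <- rownames(D)
  attr(pts, "eig") <- ev
  pts
}

.mds_dispersion <- function(coords) {
  ctr <- colMeans(coords)
  mean(sqrt(rowSums(sweep(coords, 2, ctr)^2)))
}

.pad_cols <- function(m, k) {
  if (ncol(m) >= k) return(m[, seq_len(k), drop = FALSE])
  cbind(m, matrix(0, nrow(m), k - ncol(m)))
}

#' Permutation null for regional separation in MDS space
#'
#' Builds the reference distribution against which real regional
#' dispersion is judged: provider-to-region labels are randomly permuted
#' (preserving the number of providers per region exactly), and the whole
#' region-profile, correlation-distance, classical-MDS chain is
#' recomputed per permutation. Each permuted configuration is aligned to
#' the real one by Procrustes rotation (translation + rotation, no
#' scaling), since MDS is defined only up to orthogonal transform.
#'
#' @param x a [ClaimsExperiment-class].
#' @param regions named per-provider region labels.
#' @param enrollees named per-region enrollee counts.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @param min_national_claims passed to [regionProfiles()].
#' @param k MDS dimension (default 2).
#' @return list: `real_coords`, `real_dispersion`, `perm_coords`
#'   (stacked permuted points), `perm_dispersions`, and `percentile` (the
#'   fraction of permuted dispersions strictly below the real one).
#' @export
permutationNull <- function(x, regions, enrollees, n_perm = 100, seed = 1L,
                            min_national_claims = 0, k = 2) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  regions <- regions[colnames(x)]
  rp <- regionProfiles(x, regions, enrollees, min_national_claims)
  real <- classicalMds(correlationDistance(rp), k = k)
  real <- .pad_cols(real, k)
  set.seed(as.integer(seed))
  lab_idx <- which(!is.na(regions))
  perm_disp <- numeric(n_perm)
  perm_pts <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    p <- regions
    p[lab_idx] <- regions[lab_idx][sample.int(length(lab_idx))]
    rp_b <- regionProfiles(x, p, enrollees, min_national_claims)
    co <- suppressWarnings(classicalMds(correlationDistance(rp_b), k = k))
    co <- .pad_cols(co, k)
    co <- co[rownames(real), , drop = FALSE]
    al <- vegan::procrustes(real, co, scale = FALSE, symmetric = FALSE)
    perm_pts[[b]] <- al$Yrot
    perm_disp[b] <- .mds_dispersion(al$Yrot)
  }
  list(real_coords = real,
       real_dispersion = .mds_dispersion(real),
       perm_coords = do.call(rbind, perm_pts),
       perm_dispersions = perm_disp,
       percentile = mean(perm_disp < .mds_dispersion(real)))
}

#' Pairwise region comparison with a fold band
#'
#' Compares claims-per-enrollee rates between two regions feature by
#' feature and flags features whose rate ratio exceeds `fold` (the
#' scatter-plot convention draws the band as dashed `fold`-fold lines).
#' Features with a zero rate in either region are excluded by default
#' (they cannot be placed on a log-scale plot) or handled by a
#' pseudocount.
#'
#' @param profiles a [RegionProfiles-class].
#' @param region_a,region_b region labels present in `profiles`.
#' @param fold flag threshold on max/min rate ratio (default 5).
#' @param zero_handling `"exclude"` or `"pseudocount"`.
#' @param pseudocount added to both rates under `"pseudocount"`.
#' @return data.frame `feature`, `rate_a`, `rate_b`, `ratio`, `flagged`.
#' @export
pairwiseRegionCompare <- function(profiles, region_a, region_b, fold = 5,
                                  zero_handling = c("exclude", "pseudocount"),
                                  pseudocount = 1e-6) {
  zero_handling <- match.arg(zero_handling)
  m <- regionRates(profiles)
  for (r in c(region_a, region_b))
    if (!r %in% rownames(m))
      stop(sprintf("unknown region '%s'", r), call. = FALSE)
  a <- m[region_a, ]; b <- m[region_b, ]
  feat <- colnames(m)
  if (zero_handling == "exclude") {
    keep <- a > 0 & b > 0
    a <- a[keep]; b <- b[keep]; feat <- feat[keep]
  } else {
    a <- a + pseudocount; b <- b + pseudocount
  }
  ratio <- pmax(a, b) / pmin(a, b)
  data.frame(feature = feat, rate_a = unname(a), rate_b = unname(b),
             ratio = unname(ratio), flagged = unname(ratio > fold),
             stringsAsFactors = FALSE)
}

#' Correlation between prescribing and disease-prevalence distances
#'
#' Computes the Euclidean distance matrix between per-state mean
#' prescribing vectors and likewise between per-state disease-prevalence
#' vectors, and reports the squared Pearson correlation between the two
#' matrices' upper-triangle entries (the Mantel-style statistic). A high
#' value would mean between-state prescribing structure is explained by
#' prevalence structure.
#'
#' @param prescribing states-by-classes matrix of mean prescribing
#'   vectors.
#' @param prevalence states-by-diseases matrix of prevalence (percent).
#' @return list: `prescribing_dist`, `prevalence_dist` (`dist` objects),
#'   `r_squared`, `n_states`.
#' @export
stateDistanceCorrelation <- function(prescribing, prevalence) {
  common <- intersect(rownames(prescribing), rownames(prevalence))
  common <- common[stats::complete.cases(prescribing[common, , drop = FALSE]) &
                     stats::complete.cases(prevalence[common, , drop = FALSE])]
  if (length(common) < 3)
    stop("at least 3 states with complete vectors are required", call. = FALSE)
  d1 <- stats::dist(prescribing[common, , drop = FALSE])
  d2 <- stats::dist(prevalence[common, , drop = FALSE])
  v1 <- as.numeric(d1); v2 <- as.numeric(d2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("distance correlation undefined: a distance matrix has zero variance",
         call. = FALSE)
  list(prescribing_dist = d1, prevalence_dist = d2,
       r_squared = stats::cor(v1, v2)^2, n_states = length(common))
}

#' Mann-Whitney U comparison of two samples of region fractions
#'
#' Two-sided rank-sum comparison: the exact null distribution is used for
#' combined sample sizes up to 20 (without ties), and the normal
#' approximation with tie correction above that (no continuity
#' correction, so the maximal-tie case gives p = 1).
#'
#' @param a,b non-empty numeric samples.
#' @return list with `U` (for the first sample), `p_value`, `exact`.
#' @export
compareRegionFractions <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}
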