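## Per-provider feature vectors, compositions, class aggregation, and the
## univariate skew/volume statistics of the claims landscape.

#' Build per-provider profiles at the drug or class level
#'
#' Creates the providers-by-features matrix of feature vectors. At the
#' class level, member-drug counts are summed per provider *before* any
#' normalization, so class aggregation conserves provider totals exactly.
#' With `normalize = TRUE` each provider row is divided by its total to
#' give the prescribing composition.
#'
#' @param x a [ClaimsExperiment-class].
#' @param level `"drugs"` or `"classes"`.
#' @param classMap data.frame `drug_key` -> `class`; defaults to the
#'   `class` column of `rowData(x)`. Must cover every drug when
#'   `level = "classes"`.
#' @param normalize divide rows by provider totals (default `TRUE`).
#' @return a [ProfileMatrix-class].
#' @export
buildProfiles <- function(x, level = c("drugs", "classes"), classMap = NULL,
                          normalize = TRUE) {
  level <- match.arg(level)
  cnt <- claimCounts(x)
  totals <- Matrix::colSums(cnt)
  if (level == "classes") {
    if (is.null(classMap)) {
      cls <- rowData(x)$class
      if (is.null(cls))
        stop("no classMap given and rowData(x) has no 'class' column", call. = FALSE)
      classMap <- data.frame(drug_key = rownames(x), class = cls)
    }
    cls <- classMap$class[match(rownames(x), classMap$drug_key)]
    if (anyNA(cls)) {
      offenders <- rownames(x)[is.na(cls)]
      stop(sprintf("class map does not cover %d drug(s): %s",
                   length(offenders),
                   paste(utils::head(offenders, 5), collapse = ", ")),
           call. = FALSE)
    }
    levs <- sort(unique(cls))
    agg <- Matrix::sparseMatrix(i = match(cls, levs), j = seq_along(cls),
                                x = 1, dims = c(length(levs), length(cls)),
                                dimnames = list(levs, rownames(x)))
    feat <- agg %*% cnt    # classes x providers
  } else {
    feat <- cnt
  }
  vals <- base::t(as.matrix(feat))   # providers x features
  if (normalize) {
    nz <- totals > 0
    vals[nz, ] <- vals[nz, , drop = FALSE] / totals[nz]
  }
  new("ProfileMatrix", values = vals, level = level,
      normalized = normalize, totals = stats::setNames(totals, colnames(cnt)),
      censorThreshold = censorThreshold(x), minClaims = 0)
}

#' Restrict a profile matrix to providers above a claims floor
#'
#' Retains providers whose raw (post-censoring) claim total is at least
#' `min_claims`, recording the threshold in the provenance. Applicable to
#' normalized profiles because raw totals travel with the object.
#'
#' @param profile a [ProfileMatrix-class].
#' @param min_claims minimum total claims (the figure-level analyses use
#'   1000).
#' @return the filtered [ProfileMatrix-class].
#' @export
filterMinClaims <- function(profile, min_claims) {
  keep <- profile@totals >= min_claims
  new("ProfileMatrix", values = profile@values[keep, , drop = FALSE],
      level = profile@level, normalized = profile@normalized,
      totals = profile@totals[keep],
      censorThreshold = profile@censorThreshold,
      minClaims = as.numeric(min_claims))
}

#' Per-provider diversity/volume and per-drug reach/volume summaries
#'
#' Prescribing diversity is the number of distinct drugs with surviving
#' (at/above the censoring threshold) claims for a provider; a drug's
#' prescriber fraction is the share of providers with surviving claims
#' for it.
#'
#' @param x a [ClaimsExperiment-class].
#' @return list of two data.frames: `providers` (`npi`, `unique_drugs`,
#'   `total_claims`) and `drugs` (`drug_key`, `prescriber_fraction` in
#'   percent, `total_claims`).
#' @export
diversityVolume <- function(x) {
  cnt <- claimCounts(x)
  n <- ncol(cnt)
  providers <- data.frame(
    npi = colnames(cnt),
    unique_drugs = Matrix::colSums(cnt != 0),
    total_claims = Matrix::colSums(cnt),
    row.names = NULL, stringsAsFactors = FALSE)
  drugs <- data.frame(
    drug_key = rownames(cnt),
    prescriber_fraction = 100 * Matrix::rowSums(cnt != 0) / max(1, n),
    total_claims = Matrix::rowSums(cnt),
    row.names = NULL, stringsAsFactors = FALSE)
  list(providers = providers, drugs = drugs)
}

#' Count and percentage of features meeting a threshold criterion
#'
#' @param values per-feature statistic (e.g. prescriber fractions, total
#'   claims, diversities).
#' @param threshold features with `values >= threshold` are counted.
#' @param feature_total denominator for the percentage (defaults to
#'   `length(values)`).
#' @return list with `count_meeting` and `percent` (one decimal place,
#'   the convention used for reported shares).
#' @export
thresholdSummary <- function(values, threshold, feature_total = length(values)) {
  count <- sum(values >= threshold)
  list(count_meeting = count,
       percent = shareMeeting(count, feature_total))
}

#' Percentage for a count of features meeting a criterion
#'
#' @param count_meeting number of features meeting the criterion.
#' @param feature_total total number of features.
#' @return `100 * count_meeting / feature_total`, rounded to one decimal.
#' @export
shareMeeting <- function(count_meeting, feature_total) {
  if (feature_total == 0)
    stop("percentage undefined: feature_total is 0", call. = FALSE)
  round(100 * count_meeting / feature_total, 1)
}

#' Gini concentration index with percentile-bootstrap CI
#'
#' Quantifies skew of a non-negative distribution (claim volumes across
#' providers or drugs). With values sorted ascending, \eqn{x_i \le
#' x_{i+1}},
#' \deqn{G = \frac{\sum_{i=1}^n (2i - n - 1) x_i}{n^2 \mu}.}
#' `G = 0` when all values are equal; `G` approaches 1 with increasing
#' skew. The denominator is exactly `n^2 * mu` (no small-sample
#' correction). The confidence interval is a percentile bootstrap over
#' observations.
#'
#' @param values non-negative numeric vector with at least one positive
#'   entry.
#' @param bootstrap_reps bootstrap resamples (default 1000; 0 skips the CI).
#' @param conf CI coverage (default 0.95).
#' @param seed optional seed for the bootstrap.
#' @return list with `gini`, `ci` (length-2 or `NULL`), `n`, `mu`.
#' @export
giniIndex <- function(values, bootstrap_reps = 1000, conf = 0.95, seed = NULL) {
  if (any(values < 0)) stop("Gini index requires non-negative values", call. = FALSE)
  if (!any(values > 0))
    stop("Gini index undefined: all values are zero (mu = 0)", call. = FALSE)
  g <- .gini_point(values)
  ci <- NULL
  if (bootstrap_reps > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    n <- length(values)
    reps <- vapply(seq_len(bootstrap_reps), function(b) {
      v <- values[sample.int(n, n, replace = TRUE)]
      if (!any(v > 0)) return(NA_real_)
      .gini_point(v)
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(reps, c(a, 1 - a), na.rm = TRUE))
  }
  list(gini = g, ci = ci, n = length(values), mu = mean(values))
}

.gini_point <- function(values) {
  x <- sort(values)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Split providers into high- and standard-volume cohorts
#'
#' Partitions providers at a total-claims threshold (default 25,000, the
#' high-volume cut) and compares the specialty composition of the two
#' cohorts with a chi-square test on the specialty contingency table.
#'
#' @param x a [ClaimsExperiment-class] with `specialty_description` in its
#'   provider annotations.
#' @param hv_threshold claims threshold; totals `>= hv_threshold` are
#'   high-volume.
#' @param totals per-provider totals to split on; defaults to the
#'   `total_claims` annotation if present, else post-censoring matrix sums.
#' @return list with `hv`/`sv` NPI vectors, `composition` (per-cohort
#'   specialty proportions), and `p_value` (NA with a warning when a
#'   cohort is empty).
#' @export
splitCohorts <- function(x, hv_threshold = 25000, totals = NULL) {
  if (is.null(totals)) {
    totals <- colData(x)$total_claims
    if (is.null(totals)) totals <- providerTotals(x)
  }
  totals <- as.numeric(totals)
  spec <- colData(x)$specialty_description
  if (is.null(spec)) stop("provider annotations lack specialty_description", call. = FALSE)
  hv <- totals >= hv_threshold
  cohort <- factor(ifelse(hv, "HV", "SV"), levels = c("HV", "SV"))
  comp <- prop.table(table(specialty = spec, cohort = cohort), margin = 2)
  p <- NA_real_
  if (!any(hv) || all(hv)) {
    warning("one cohort is empty; composition comparison skipped")
  } else {
    tab <- table(spec, cohort)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  }
  list(hv = colnames(x)[hv], sv = colnames(x)[!hv],
       composition = comp, p_value = p)
}

#' State provider shares versus enrollee shares
#'
#' Computes each state's share of providers and of Part D enrollees (both
#' in percent, each summing to 100), and fits provider share on enrollee
#' share by ordinary least squares. Under exact proportionality the slope
#' is 1 with R-squared 1; deviations flag states over- or under-supplied
#' with (high-volume) prescribers relative to their enrollee base.
#'
#' @param x a [ClaimsExperiment-class] with `nppes_provider_state`.
#' @param state_enrollees data.frame with columns `state`, `enrollees`.
#' @param providers optional NPI subset (e.g. the HV cohort).
#' @return list with `shares` (data.frame state, provider_share,
#'   enrollee_share), `slope`, `r_squared`, and `degenerate` (TRUE when
#'   fewer than 3 states admit no meaningful fit).
#' @export
stateShares <- function(x, state_enrollees, providers = NULL) {
  if (sum(state_enrollees$enrollees) <= 0)
    stop("enrollee counts are zero everywhere", call. = FALSE)
  st <- colData(x)$nppes_provider_state
  names(st) <- colnames(x)
  if (!is.null(providers)) st <- st[providers]
  states <- sort(unique(c(st, state_enrollees$state)))
  ptab <- table(factor(st, levels = states))
  etab <- stats::setNames(rep(0, length(states)), states)
  etab[state_enrollees$state] <- state_enrollees$enrollees
  shares <- data.frame(
    state = states,
    provider_share = 100 * as.numeric(ptab) / sum(ptab),
    enrollee_share = 100 * as.numeric(etab) / sum(etab),
    stringsAsFactors = FALSE)
  degenerate <- length(states) < 3
  slope <- NA_real_; r2 <- NA_real_
  if (!degenerate) {
    fit <- stats::lm(provider_share ~ enrollee_share, data = shares)
    slope <- unname(stats::coef(fit)["enrollee_share"])
    r2 <- summary(fit)$r.squared
  } else {
    warning("fewer than 3 states: share fit is degenerate")
  }
  list(shares = shares, slope = slope, r_squared = r2, degenerate = degenerate)
}
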