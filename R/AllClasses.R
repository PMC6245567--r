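#' @import methods
#' @importFrom Matrix Matrix sparseMatrix colSums rowSums t drop0
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#'   "colData<-" "rowData<-"
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

#' ClaimsExperiment: a censored provider-by-drug claims matrix
#'
#' `ClaimsExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' to hold a sparse matrix of prescription claim counts with drugs as rows
#' (features) and providers as columns (samples). Row metadata carries the
#' drug annotations (`drug_name`, `generic_name` and, optionally, a drug
#' `class`); column metadata carries the provider annotations (`npi`,
#' `specialty`, `state`, `county_fips`, `cbsa`, `total_claims`). The
#' privacy-censoring threshold that has been applied to the counts is
#' recorded in `metadata(x)$censor_threshold`: every stored non-zero count
#' is at least that threshold.
#'
#' Drug identity is the (brand name, generic name) pair, which is unique in
#' PUF-shaped data where a single brand or generic name alone is not; row
#' names are the `"brand|generic"` key.
#'
#' @slot .  See [SummarizedExperiment::SummarizedExperiment]; the single
#'   assay is named `"counts"`.
#' @seealso [claimsExperiment()], [applyCensoring()], [dropEmpty()]
#' @export
setClass("ClaimsExperiment", contains = "SummarizedExperiment")

setValidity("ClaimsExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    v <- if (inherits(cnt, "sparseMatrix")) cnt@x else as.numeric(cnt)
    if (length(v) && any(v < 0)) msg <- c(msg, "claim counts must be non-negative")
    thr <- metadata(object)$censor_threshold
    if (is.null(thr)) msg <- c(msg, "metadata(x)$censor_threshold is required")
    else if (thr < 0) msg <- c(msg, "censor_threshold must be >= 0")
    else {
      nz <- v[v != 0]
      if (length(nz) && any(nz < thr))
        msg <- c(msg, sprintf("non-zero counts below the recorded censor_threshold (%s)", thr))
    }
  }
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate provider IDs (NPIs)")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate drug keys")
  if (length(msg)) msg else TRUE
})

#' Construct a ClaimsExperiment
#'
#' @param counts drugs-by-providers matrix of claim counts (coerced to a
#'   sparse `Matrix`); row names are drug keys, column names are NPIs.
#' @param providerData `data.frame`/`DataFrame` of provider annotations,
#'   one row per column of `counts`.
#' @param drugData `data.frame`/`DataFrame` of drug annotations, one row
#'   per row of `counts`.
#' @param censorThreshold censoring threshold already applied to `counts`
#'   (0 for uncensored data).
#' @return a [ClaimsExperiment-class] object.
#' @export
claimsExperiment <- function(counts, providerData = NULL, drugData = NULL,
                             censorThreshold = 0) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- Matrix::drop0(counts)
  if (is.null(providerData))
    providerData <- DataFrame(npi = colnames(counts))
  if (is.null(drugData))
    drugData <- DataFrame(drug_key = rownames(counts))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = drugData, colData = providerData)
  metadata(se)$censor_threshold <- as.numeric(censorThreshold)
  new("ClaimsExperiment", se)
}

#' @describeIn claimsExperiment the sparse drugs-by-providers count matrix
#' @param x a `ClaimsExperiment`
#' @export
claimCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn claimsExperiment the censoring threshold recorded on `x`
#' @export
censorThreshold <- function(x) metadata(x)$censor_threshold

#' @describeIn claimsExperiment per-provider total (post-censoring) claims
#' @export
providerTotals <- function(x) Matrix::colSums(claimCounts(x))

#' @describeIn claimsExperiment per-drug national total (post-censoring) claims
#' @export
drugTotals <- function(x) Matrix::rowSums(claimCounts(x))

setMethod("show", "ClaimsExperiment", function(object) {
  cat("ClaimsExperiment:", ncol(object), "providers x", nrow(object), "drugs\n")
  cat("  censor threshold:", censorThreshold(object), "\n")
  cnt <- claimCounts(object)
  cat("  non-zero cells:", length(cnt@x), sprintf("(%.2f%% dense)\n",
      100 * length(cnt@x) / max(1, prod(dim(cnt)))))
  cat("  provider annotations:", paste(colnames(colData(object)), collapse = ", "), "\n")
})

#' ProfileMatrix: per-provider feature vectors
#'
#' Providers-by-features matrix of claim counts or compositions, at the
#' individual-drug or drug-class level. When `normalized` is `TRUE` each
#' non-empty row sums to one (the provider's prescribing composition).
#' Raw provider totals are kept alongside so volume filters remain
#' applicable after normalization.
#'
#' @slot values providers-by-features numeric matrix.
#' @slot level `"drugs"` or `"classes"`.
#' @slot normalized logical; compositions vs raw counts.
#' @slot totals named numeric; per-provider raw claim totals.
#' @slot censorThreshold numeric; provenance of the source matrix.
#' @slot minClaims numeric; minimum-claims filter applied (0 = none).
#' @export
setClass("ProfileMatrix", representation(
  values = "matrix", level = "character", normalized = "logical",
  totals = "numeric", censorThreshold = "numeric", minClaims = "numeric"))

setValidity("ProfileMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@totals))
    msg <- c(msg, "totals must have one entry per provider row")
  if (object@normalized && nrow(object@values)) {
    rs <- rowSums(object@values)
    bad <- abs(rs - 1) > 1e-9 & rs != 0
    if (any(bad)) msg <- c(msg, "normalized rows must sum to 1 (or be all-zero)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ProfileMatrix-class the providers-by-features matrix
#' @param x a `ProfileMatrix`
#' @export
profileValues <- function(x) x@values

#' @describeIn ProfileMatrix-class feature level ("drugs" or "classes")
#' @export
featureLevel <- function(x) x@level

#' @describeIn ProfileMatrix-class raw per-provider claim totals
#' @export
profileTotals <- function(x) x@totals

setMethod("show", "ProfileMatrix", function(object) {
  cat("ProfileMatrix:", nrow(object@values), "providers x",
      ncol(object@values), object@level, "\n")
  cat("  normalized:", object@normalized,
      "| censor threshold:", object@censorThreshold,
      "| min claims:", object@minClaims, "\n")
})

#' Embedding2D: a selected two-dimensional t-SNE embedding
#'
#' Coordinates for every provider plus the final Kullback-Leibler cost of
#' each restart; the stored coordinates are those of the restart with the
#' minimum final cost.
#'
#' @slot coords n-by-2 matrix, row names the provider IDs.
#' @slot costs final KL divergence of each restart.
#' @slot selected index of the minimum-cost restart.
#' @slot params list of embedding parameters used.
#' @export
setClass("Embedding2D", representation(
  coords = "matrix", costs = "numeric", selected = "integer", params = "list"))

setValidity("Embedding2D", function(object) {
  msg <- character()
  if (ncol(object@coords) != 2) msg <- c(msg, "coords must have 2 columns")
  if (length(object@costs)) {
    if (object@selected < 1 || object@selected > length(object@costs))
      msg <- c(msg, "selected restart index out of range")
    else if (object@costs[object@selected] > min(object@costs) + 1e-12)
      msg <- c(msg, "selected restart must have the minimum cost")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Embedding2D-class the n-by-2 coordinate matrix
#' @param x an `Embedding2D`
#' @export
embeddingCoords <- function(x) x@coords

#' @describeIn Embedding2D-class per-restart final KL costs
#' @export
embeddingCosts <- function(x) x@costs

setMethod("show", "Embedding2D", function(object) {
  cat("Embedding2D:", nrow(object@coords), "points;",
      length(object@costs), "restart(s); selected run", object@selected,
      sprintf("(KL cost %.5f)\n", object@costs[object@selected]))
})

#' RegionProfiles: claims-per-enrollee region profiles
#'
#' Regions-by-features matrix of claims per Part D enrollee, restricted to
#' features passing a national-claims filter, with the per-region enrollee
#' counts used for the normalization.
#'
#' @slot rates regions-by-features matrix of claims per enrollee.
#' @slot enrollees named numeric, enrollee count per region (> 0).
#' @slot minNationalClaims the strict national-claims filter applied.
#' @export
setClass("RegionProfiles", representation(
  rates = "matrix", enrollees = "numeric", minNationalClaims = "numeric"))

setValidity("RegionProfiles", function(object) {
  msg <- character()
  if (any(object@rates < 0)) msg <- c(msg, "rates must be non-negative")
  if (nrow(object@rates) != length(object@enrollees))
    msg <- c(msg, "one enrollee count per region row is required")
  if (length(object@enrollees) && any(object@enrollees <= 0))
    msg <- c(msg, "enrollee counts must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn RegionProfiles-class the regions-by-features rate matrix
#' @param x a `RegionProfiles`
#' @export
regionRates <- function(x) x@rates

#' @describeIn RegionProfiles-class enrollee counts per region
#' @export
regionEnrollees <- function(x) x@enrollees

setMethod("show", "RegionProfiles", function(object) {
  cat("RegionProfiles:", nrow(object@rates), "regions x",
      ncol(object@rates), "features (national claims >",
      object@minNationalClaims, ")\n")
})
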