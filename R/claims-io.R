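## Ingest of PUF-shaped claims tables, CMS small-cell censoring, and
## geography/enrollee linkage.

.drug_key <- function(drug_name, generic_name) paste(drug_name, generic_name, sep = "|")

.require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("file '%s' is missing required column(s): %s",
                 file, paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read PUF-shaped claims tables into a ClaimsExperiment
#'
#' Reads the three-table release layout: a provider table keyed by NPI, a
#' drug table keyed by the (brand, generic) name pair, and a long-format
#' provider-drug table of claim counts (a bipartite provider/drug graph).
#' The censoring threshold is applied on ingest so the resulting matrix
#' satisfies the ClaimsExperiment invariant.
#'
#' @param provider_file CSV with columns `npi`, `specialty_description`,
#'   `nppes_provider_state` (plus any extra annotation columns, retained).
#' @param drug_file CSV with columns `drug_name`, `generic_name` (a
#'   `class` column, if present, is retained as the drug-class label).
#' @param link_file CSV with columns `npi`, `drug_name`, `generic_name`,
#'   `total_claim_count`.
#' @param censor_threshold small-cell censoring threshold; counts strictly
#'   below it are set to zero (default 11, the CMS rule).
#' @param keep_empty keep providers/drugs with no surviving claims as
#'   all-zero columns/rows (default `FALSE` drops them, reporting counts).
#' @param sep field delimiter for all three files.
#' @return a [ClaimsExperiment-class].
#' @export
readPuf <- function(provider_file, drug_file, link_file,
                    censor_threshold = 11, keep_empty = FALSE, sep = ",") {
  prov <- utils::read.table(provider_file, header = TRUE, sep = sep,
                            colClasses = "character", check.names = FALSE,
                            quote = "\"", comment.char = "")
  drug <- utils::read.table(drug_file, header = TRUE, sep = sep,
                            colClasses = "character", check.names = FALSE,
                            quote = "\"", comment.char = "")
  link <- utils::read.table(link_file, header = TRUE, sep = sep,
                            colClasses = "character", check.names = FALSE,
                            quote = "\"", comment.char = "")
  .require_cols(prov, c("npi", "specialty_description", "nppes_provider_state"),
                provider_file)
  .require_cols(drug, c("drug_name", "generic_name"), drug_file)
  .require_cols(link, c("npi", "drug_name", "generic_name", "total_claim_count"),
                link_file)
  if (anyDuplicated(prov$npi))
    stop("duplicate NPI rows in the provider table", call. = FALSE)
  dkey <- .drug_key(drug$drug_name, drug$generic_name)
  if (anyDuplicated(dkey))
    stop("duplicate (drug_name, generic_name) rows in the drug table", call. = FALSE)
  lkey <- .drug_key(link$drug_name, link$generic_name)
  if (anyDuplicated(paste(link$npi, lkey, sep = "\r")))
    stop("duplicate (npi, drug) rows in the provider-drug link table", call. = FALSE)

  unknown <- setdiff(link$npi, prov$npi)
  if (length(unknown))
    stop(sprintf("link table references %d NPI(s) absent from the provider table",
                 length(unknown)), call. = FALSE)
  unknown <- setdiff(lkey, dkey)
  if (length(unknown))
    stop(sprintf("link table references %d drug key(s) absent from the drug table",
                 length(unknown)), call. = FALSE)

  counts <- Matrix::sparseMatrix(
    i = match(lkey, dkey), j = match(link$npi, prov$npi),
    x = as.numeric(link$total_claim_count),
    dims = c(length(dkey), nrow(prov)),
    dimnames = list(dkey, prov$npi))

  pd <- DataFrame(prov, row.names = prov$npi, check.names = FALSE)
  dd <- DataFrame(drug, row.names = dkey, check.names = FALSE)
  x <- claimsExperiment(counts, providerData = pd, drugData = dd,
                        censorThreshold = 0)
  x <- applyCensoring(x, censor_threshold)
  if (!keep_empty) x <- dropEmpty(x)
  x
}

#' Apply the small-cell privacy censoring rule
#'
#' Sets every claim count strictly below `threshold` to zero, leaving
#' counts greater than or equal to it untouched (so a count equal to the
#' threshold survives), and records the threshold. Censoring at a given
#' threshold is idempotent, and censoring at `t1` followed by `t2 >= t1`
#' equals censoring at `t2` alone.
#'
#' @param x a [ClaimsExperiment-class] or a (possibly sparse) numeric matrix.
#' @param threshold non-negative censoring threshold (default 11).
#' @return same class as `x`, censored.
#' @export
setGeneric("applyCensoring", function(x, threshold = 11) standardGeneric("applyCensoring"))

.censor_values <- function(m, threshold) {
  if (inherits(m, "sparseMatrix")) {
    m@x[m@x < threshold] <- 0
    Matrix::drop0(m)
  } else {
    m[m < threshold] <- 0
    m
  }
}

#' @rdname applyCensoring
#' @export
setMethod("applyCensoring", "ClaimsExperiment", function(x, threshold = 11) {
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0)
    stop("threshold must be a single non-negative number", call. = FALSE)
  cnt <- .censor_values(claimCounts(x), threshold)
  SummarizedExperiment::assay(x, "counts") <- cnt
  metadata(x)$censor_threshold <- max(as.numeric(threshold),
                                      censorThreshold(x))
  validObject(x)
  x
})

#' @rdname applyCensoring
#' @export
setMethod("applyCensoring", "ANY", function(x, threshold = 11) {
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0)
    stop("threshold must be a single non-negative number", call. = FALSE)
  .censor_values(x, threshold)
})

#' Drop all-zero providers and drugs
#'
#' Removes providers (columns) and drugs (rows) with no surviving claims
#' after censoring, reporting how many of each were removed. In
#' PUF-shaped data this is the step that reduces the nominal provider
#' universe to the providers with at least one cell at or above the
#' censoring threshold.
#'
#' @param x a [ClaimsExperiment-class].
#' @return the reduced object; attributes `providers_dropped` and
#'   `drugs_dropped` carry the removal counts.
#' @export
dropEmpty <- function(x) {
  cnt <- claimCounts(x)
  keep_p <- Matrix::colSums(cnt != 0) > 0
  keep_d <- Matrix::rowSums(cnt != 0) > 0
  if (!any(keep_p)) warning("all providers censored to zero; result is empty")
  out <- x[keep_d, keep_p]
  attr(out, "providers_dropped") <- sum(!keep_p)
  attr(out, "drugs_dropped") <- sum(!keep_d)
  out
}

#' Attach CBSA geography and enrollee counts to providers
#'
#' Joins a county-FIPS to CBSA crosswalk onto the provider annotations
#' (providers in counties outside any CBSA get `NA`, which is tolerated:
#' rural counties are not covered by metropolitan definitions), and
#' returns per-region Part D enrollee counts for downstream
#' claims-per-enrollee normalization.
#'
#' @param x a [ClaimsExperiment-class] whose `colData` has `county_fips`.
#' @param crosswalk data.frame with columns `county_fips` (5-digit,
#'   zero-padded text) and `cbsa`.
#' @param enrollees data.frame with columns `region` and `enrollees`.
#' @return list with elements `claims` (annotated object) and
#'   `enrollees` (named numeric vector).
#' @export
attachGeography <- function(x, crosswalk, enrollees) {
  .require_cols(crosswalk, c("county_fips", "cbsa"), "crosswalk")
  .require_cols(enrollees, c("region", "enrollees"), "enrollee table")
  bad <- !grepl("^[0-9]{5}$", crosswalk$county_fips)
  if (any(bad))
    stop(sprintf("malformed FIPS code(s) in crosswalk (must be 5 digits): %s",
                 paste(utils::head(crosswalk$county_fips[bad], 5), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(crosswalk$county_fips))
    stop("a county FIPS code maps to more than one CBSA", call. = FALSE)
  fips <- colData(x)$county_fips
  if (is.null(fips)) stop("provider annotations lack a county_fips column", call. = FALSE)
  colData(x)$cbsa <- crosswalk$cbsa[match(fips, crosswalk$county_fips)]
  enr <- stats::setNames(as.numeric(enrollees$enrollees), enrollees$region)
  list(claims = x, enrollees = enr)
}
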