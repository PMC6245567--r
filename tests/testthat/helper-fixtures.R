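# Small fixtures built in code.

# ClaimsExperiment from a dense drugs-x-providers matrix.
tiny_claims <- function(counts, censor = 0, states = NULL, fips = NULL,
                        specialties = NULL, classes = NULL) {
  m <- nrow(counts); n <- ncol(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("D%02d|g%02d", seq_len(m), seq_len(m))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("1%09d", seq_len(n))
  key <- rownames(counts)
  brand <- sub("\\|.*$", "", key); gen <- sub("^.*\\|", "", key)
  pd <- S4Vectors::DataFrame(
    npi = colnames(counts),
    specialty_description = if (is.null(specialties)) rep("GP", n) else specialties,
    nppes_provider_state = if (is.null(states)) rep("NY", n) else states,
    row.names = colnames(counts))
  if (!is.null(fips)) pd$county_fips <- fips
  dd <- S4Vectors::DataFrame(drug_name = brand, generic_name = gen,
                             row.names = key)
  if (!is.null(classes)) dd$class <- classes
  x <- claimsExperiment(counts, providerData = pd, drugData = dd,
                        censorThreshold = 0)
  if (censor > 0) x <- applyCensoring(x, censor)
  x
}

# Small synthetic population shared across tests (cached per session).
small_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generatePopulation(simulationConfig(
        n_providers = 250, n_drugs = 100, n_classes = 20,
        specialties = specialtySpecs(100, 4), regions = regionSpecs(3),
        seed = 42))
    cache
  }
})
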