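## Synthetic PUF-shaped claims populations with planted ground truth:
## specialty-specific Dirichlet prescribing profiles, log-normal volume
## skew, multiplicative regional effects, and small-cell censoring.

.state_pool <- c("NY", "TX", "CA", "FL", "IL", "PA", "OH", "GA", "NC", "MI",
                 "WA", "MA", "TN", "AZ", "MO", "MD", "WI", "MN", "CO", "AL")

#' Specialty specifications for the claims simulator
#'
#' Builds a list of specialty specs whose Dirichlet concentration vector
#' is `tau` times a characteristic mean profile: each specialty
#' concentrates `block_share` of its claims on its own contiguous block
#' of drugs with Zipf (1/rank) weights -- every provider in a specialty
#' shares the same few workhorse drugs, prescribed at provider-varying
#' proportions -- plus a uniform baseline over the whole formulary giving
#' the long sparse tail of occasional prescriptions seen in real claims.
#' Larger `tau` means less provider-to-provider variability around the
#' specialty mean.
#'
#' @param n_drugs number of drugs in the simulated formulary.
#' @param n_specialties number of specialties (equal prevalence weights).
#' @param tau Dirichlet concentration (precision) around the specialty
#'   mean profile; default 30.
#' @param block_share share of a specialty's claims on its own drug block
#'   (default 0.9).
#' @param volume_scale per-specialty multiplier on expected claim volume
#'   (length 1 or `n_specialties`); lets one specialty be systematically
#'   high-volume.
#' @return list of specs `list(name, weight, concentration, volume_scale)`.
#' @export
specialtySpecs <- function(n_drugs, n_specialties = 5, tau = 30,
                           block_share = 0.9, volume_scale = 1) {
  volume_scale <- rep_len(volume_scale, n_specialties)
  block <- if (n_specialties == 1) list(seq_len(n_drugs)) else
    split(seq_len(n_drugs),
          cut(seq_len(n_drugs), n_specialties, labels = FALSE))
  lapply(seq_len(n_specialties), function(s) {
    mean_prof <- rep((1 - block_share) / n_drugs, n_drugs)
    zipf <- 1 / seq_along(block[[s]])
    mean_prof[block[[s]]] <- mean_prof[block[[s]]] +
      block_share * zipf / sum(zipf)
    list(name = sprintf("Specialty_%02d", s), weight = 1 / n_specialties,
         concentration = tau * mean_prof, volume_scale = volume_scale[s])
  })
}

#' Region specifications for the claims simulator
#'
#' Each region carries a provider share, a home state, and a per-drug
#' multiplicative effect applied to provider profiles before
#' renormalization. `effect_sd = 0` gives exchangeable regions (no planted
#' geographic signal); positive values plant log-normal per-drug regional
#' effects, the mechanism used to emulate metropolitan-area divergence.
#'
#' @param n_regions number of regions.
#' @param effect_sd standard deviation of log effects (0 = no effect).
#' @param shares provider shares (default equal; must sum to 1).
#' @return list of specs `list(name, share, effect_sd, state)`.
#' @export
regionSpecs <- function(n_regions = 3, effect_sd = 0, shares = NULL) {
  if (is.null(shares)) shares <- rep(1 / n_regions, n_regions)
  lapply(seq_len(n_regions), function(r) {
    list(name = sprintf("CBSA_%02d", r), share = shares[r],
         effect_sd = effect_sd, state = .state_pool[(r - 1) %% length(.state_pool) + 1])
  })
}

#' Simulation configuration for a synthetic claims population
#'
#' Defines the study conditions of a simulated PUF-shaped population.
#' Defaults: a mid-sized population of 600 providers over a 150-drug,
#' 30-class formulary with five equally prevalent specialties; per-provider
#' total claims drawn log-normal (`meanlog = 6.2`, `sdlog = 1.3`, median
#' about 490 claims with a heavy right tail so a fraction of a percent of
#' providers exceed 25,000 claims); 5% mixed-practice providers drawing a
#' 50/50 mixture of two specialty profiles; three exchangeable regions; and
#' the CMS censoring threshold of 11.
#'
#' @param n_providers,n_drugs,n_classes population dimensions; every drug
#'   belongs to exactly one of `n_classes` contiguous classes.
#' @param specialties list of specialty specs (see [specialtySpecs()]).
#' @param volume_meanlog,volume_sdlog log-normal parameters for per-provider
#'   total claims.
#' @param regions list of region specs (see [regionSpecs()]).
#' @param mixed_fraction proportion of providers with mixed practice.
#' @param censor_threshold small-cell censoring threshold (default 11).
#' @param enrollees_per_region named numeric; default is 40 enrollees per
#'   expected provider in the region.
#' @param disease_link `NULL`, or `list(strength, noise_sd)` to derive the
#'   regional effects from latent per-region disease-prevalence vectors via
#'   a linear map plus noise.
#' @param n_diseases number of latent disease-prevalence conditions.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return validated config list of class `rx_sim_config`.
#' @export
simulationConfig <- function(n_providers = 600, n_drugs = 150, n_classes = 30,
                             specialties = specialtySpecs(n_drugs),
                             volume_meanlog = 6.2, volume_sdlog = 1.3,
                             regions = regionSpecs(3),
                             mixed_fraction = 0.05, censor_threshold = 11,
                             enrollees_per_region = NULL,
                             disease_link = NULL, n_diseases = 13,
                             seed = 1L) {
  cfg <- list(n_providers = n_providers, n_drugs = n_drugs,
              n_classes = n_classes, specialties = specialties,
              volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
              regions = regions, mixed_fraction = mixed_fraction,
              censor_threshold = censor_threshold,
              enrollees_per_region = enrollees_per_region,
              disease_link = disease_link, n_diseases = n_diseases,
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  class(cfg) <- "rx_sim_config"
  cfg
}

.validate_sim_config <- function(cfg) {
  stop_field <- function(field, why)
    stop(sprintf("invalid simulation config: field '%s' %s", field, why),
         call. = FALSE)
  for (f in c("n_providers", "n_drugs", "n_classes"))
    if (cfg[[f]] < 1) stop_field(f, "must be a positive count")
  if (cfg$n_classes > cfg$n_drugs) stop_field("n_classes", "cannot exceed n_drugs")
  w <- vapply(cfg$specialties, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop_field("specialties", "weights must sum to 1")
  for (sp in cfg$specialties)
    if (length(sp$concentration) != cfg$n_drugs || any(sp$concentration <= 0))
      stop_field("specialties", "needs a positive concentration vector of length n_drugs")
  s <- vapply(cfg$regions, `[[`, numeric(1), "share")
  if (abs(sum(s) - 1) > 1e-9) stop_field("regions", "shares must sum to 1")
  if (cfg$mixed_fraction < 0 || cfg$mixed_fraction > 1)
    stop_field("mixed_fraction", "must lie in [0, 1]")
  if (cfg$censor_threshold < 0) stop_field("censor_threshold", "must be >= 0")
  invisible(TRUE)
}

.rdirichlet1 <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  if (sum(g) == 0) g[which.max(conc)] <- 1
  g / sum(g)
}

#' Generate a synthetic claims population with known ground truth
#'
#' Draws, per provider: a specialty (by prevalence weight), a region (by
#' share), a prescribing profile from the specialty's Dirichlet
#' concentration (mixed-practice providers average two specialty draws
#' 50/50), multiplied by the region's per-drug effect and renormalized; a
#' total claim volume from the log-normal volume model (times the
#' specialty's volume scale); and a multinomial allocation of that volume
#' over drugs. Small-cell censoring is then applied at the configured
#' threshold.
#'
#' @param config a config from [simulationConfig()].
#' @return list with elements:
#'   \describe{
#'     \item{claims}{censored [ClaimsExperiment-class] with full provider
#'       annotations (`npi`, `specialty_description`,
#'       `nppes_provider_state`, `county_fips`, `cbsa`, `total_claims`).}
#'     \item{classMap}{data.frame `drug_key` -> `class` (every drug mapped
#'       exactly once).}
#'     \item{crosswalk}{county FIPS -> CBSA crosswalk used.}
#'     \item{enrollees}{named per-region enrollee counts.}
#'     \item{truth}{ground truth: specialty/region labels, drawn volumes,
#'       the uncensored count matrix, per-region effect vectors, and (when
#'       `disease_link` is set) per-region disease-prevalence vectors.}
#'   }
#' @export
generatePopulation <- function(config) {
  .validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_providers; m <- config$n_drugs
  drug_names <- sprintf("DRUG_%03d", seq_len(m))
  generic_names <- sprintf("generic_%03d", seq_len(m))
  dkey <- .drug_key(drug_names, generic_names)
  classes <- sprintf("CLASS_%02d",
                     cut(seq_len(m), config$n_classes, labels = FALSE))

  spec_names <- vapply(config$specialties, `[[`, character(1), "name")
  spec_w <- vapply(config$specialties, `[[`, numeric(1), "weight")
  spec_scale <- vapply(config$specialties, function(s)
    if (is.null(s$volume_scale)) 1 else s$volume_scale, numeric(1))
  region_names <- vapply(config$regions, `[[`, character(1), "name")
  region_share <- vapply(config$regions, `[[`, numeric(1), "share")
  region_state <- vapply(config$regions, `[[`, character(1), "state")

  ## per-region latent disease prevalence + linear-map-plus-noise effects
  prevalence <- NULL
  effects <- matrix(1, length(config$regions), m,
                    dimnames = list(region_names, dkey))
  if (!is.null(config$disease_link)) {
    dl <- config$disease_link
    prevalence <- matrix(stats::runif(length(region_names) * config$n_diseases,
                                      5, 25),
                         length(region_names), config$n_diseases,
                         dimnames = list(region_names,
                                         sprintf("disease_%02d", seq_len(config$n_diseases))))
    L <- matrix(stats::rnorm(m * config$n_diseases), m, config$n_diseases)
    for (r in seq_along(region_names)) {
      z <- as.numeric(L %*% prevalence[r, ])
      z <- (z - mean(z)) / stats::sd(z)
      effects[r, ] <- exp(dl$strength * z +
                            stats::rnorm(m, 0, dl$noise_sd))
    }
  }
  for (r in seq_along(config$regions)) {
    rs <- config$regions[[r]]
    if (!is.null(rs[["effect"]])) effects[r, ] <- rs[["effect"]]
    else if (!is.null(rs[["effect_sd"]]) && rs[["effect_sd"]] > 0)
      effects[r, ] <- effects[r, ] * exp(stats::rnorm(m, 0, rs[["effect_sd"]]))
  }

  spec_idx <- sample.int(length(spec_names), n, replace = TRUE, prob = spec_w)
  region_idx <- sample.int(length(region_names), n, replace = TRUE,
                           prob = region_share)
  mixed <- stats::runif(n) < config$mixed_fraction & length(spec_names) > 1

  volumes <- pmax(1, round(stats::rlnorm(n, config$volume_meanlog,
                                         config$volume_sdlog) *
                             spec_scale[spec_idx]))

  counts <- matrix(0, m, n)
  for (i in seq_len(n)) {
    p <- .rdirichlet1(config$specialties[[spec_idx[i]]]$concentration)
    if (mixed[i]) {
      cand <- setdiff(seq_along(spec_names), spec_idx[i])
      other <- cand[sample.int(length(cand), 1)]
      p <- (p + .rdirichlet1(config$specialties[[other]]$concentration)) / 2
    }
    p <- p * effects[region_idx[i], ]
    p <- p / sum(p)
    counts[, i] <- stats::rmultinom(1, volumes[i], p)
  }
  npi <- sprintf("1%09d", seq_len(n))
  dimnames(counts) <- list(dkey, npi)

  ## 3 synthetic counties per region; crosswalk maps each to its CBSA
  crosswalk <- do.call(rbind, lapply(seq_along(region_names), function(r)
    data.frame(county_fips = sprintf("%02d0%02d", r, 1:3),
               cbsa = region_names[r], stringsAsFactors = FALSE)))
  county <- vapply(region_idx, function(r)
    sprintf("%02d0%02d", r, sample.int(3, 1)), character(1))

  enr <- config$enrollees_per_region
  if (is.null(enr))
    enr <- stats::setNames(round(region_share * n * 40), region_names)

  pd <- DataFrame(npi = npi,
                  specialty_description = spec_names[spec_idx],
                  nppes_provider_state = region_state[region_idx],
                  county_fips = county,
                  cbsa = region_names[region_idx],
                  total_claims = volumes,
                  row.names = npi)
  dd <- DataFrame(drug_name = drug_names, generic_name = generic_names,
                  class = classes, row.names = dkey)
  uncensored <- Matrix::Matrix(counts, sparse = TRUE)
  x <- claimsExperiment(uncensored, providerData = pd, drugData = dd,
                        censorThreshold = 0)
  x <- applyCensoring(x, config$censor_threshold)

  list(claims = x,
       classMap = data.frame(drug_key = dkey, class = classes,
                             stringsAsFactors = FALSE),
       crosswalk = crosswalk,
       enrollees = enr,
       truth = list(specialty = stats::setNames(spec_names[spec_idx], npi),
                    region = stats::setNames(region_names[region_idx], npi),
                    mixed = stats::setNames(mixed, npi),
                    volumes = stats::setNames(volumes, npi),
                    uncensored = uncensored,
                    region_effects = effects,
                    prevalence = prevalence))
}

#' Write a ClaimsExperiment as three PUF-shaped CSV tables
#'
#' Emits the provider, drug, and long-format provider-drug tables under
#' the CMS column naming convention. Only non-zero (surviving) cells are
#' written to the link table, so the round trip through [readPuf()] is
#' lossless on censored data.
#'
#' @param x a [ClaimsExperiment-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"puf"`).
#' @return (invisibly) named character vector of the three file paths.
#' @export
writePufTables <- function(x, dir, prefix = "puf") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(provider = file.path(dir, paste0(prefix, "_providers.csv")),
             drug = file.path(dir, paste0(prefix, "_drugs.csv")),
             link = file.path(dir, paste0(prefix, "_links.csv")))
  prov <- as.data.frame(colData(x))
  if (!nrow(prov)) prov <- data.frame(npi = character(),
                                      specialty_description = character(),
                                      nppes_provider_state = character())
  utils::write.csv(prov, paths["provider"], row.names = FALSE, quote = TRUE)
  dd <- as.data.frame(rowData(x))
  if (!nrow(dd)) dd <- data.frame(drug_name = character(),
                                  generic_name = character())
  utils::write.csv(dd, paths["drug"], row.names = FALSE, quote = TRUE)
  cnt <- claimCounts(x)
  trip <- as.data.frame(Matrix::summary(methods::as(cnt, "TsparseMatrix")))
  if (nrow(trip)) {
    link <- data.frame(npi = colnames(cnt)[trip$j],
                       drug_name = rowData(x)$drug_name[trip$i],
                       generic_name = rowData(x)$generic_name[trip$i],
                       total_claim_count = trip$x,
                       stringsAsFactors = FALSE)
    link <- link[order(link$npi, link$drug_name), , drop = FALSE]
  } else {
    link <- data.frame(npi = character(), drug_name = character(),
                       generic_name = character(),
                       total_claim_count = numeric())
  }
  utils::write.csv(link, paths["link"], row.names = FALSE, quote = TRUE)
  invisible(paths)
}

#' Simulate per-state prescribing and disease-prevalence profiles
#'
#' Generates mean per-state drug-class prescribing vectors together with
#' per-state disease-prevalence vectors, either affinely linked or
#' independent. The affine link is a similarity-type map (orthonormal
#' rows, uniform scale, offset) plus Gaussian noise, so between-state
#' prescribing distances are exactly proportional to prevalence distances
#' up to the noise -- a tunable ground truth for the distance-correlation
#' analysis. Used to study how much of the between-state prescribing
#' distance structure is explained by disease-prevalence distance
#' structure.
#'
#' @param n_states number of states.
#' @param n_classes prescribing feature dimension (default 68 classes).
#' @param n_diseases prevalence feature dimension (default 13 conditions).
#' @param link `"affine"` or `"independent"`.
#' @param noise_sd Gaussian noise added to the affine image.
#' @param seed integer seed.
#' @return list with matrices `prescribing` (states x classes) and
#'   `prevalence` (states x diseases, in percent).
#' @export
simulateStateProfiles <- function(n_states = 30, n_classes = 68,
                                  n_diseases = 13,
                                  link = c("affine", "independent"),
                                  noise_sd = 0.05, seed = 1L) {
  link <- match.arg(link)
  set.seed(as.integer(seed))
  states <- sprintf("ST%02d", seq_len(n_states))
  prevalence <- matrix(stats::runif(n_states * n_diseases, 2, 30),
                       n_states, n_diseases,
                       dimnames = list(states,
                                       sprintf("disease_%02d", seq_len(n_diseases))))
  if (link == "affine") {
    # orthonormal rows times a scale: a similarity, so distances transfer
    A <- 2 * t(qr.Q(qr(matrix(stats::rnorm(n_classes * n_diseases),
                              n_classes, n_diseases))))
    b <- stats::rnorm(n_classes)
    prescribing <- prevalence %*% A +
      matrix(b, n_states, n_classes, byrow = TRUE) +
      matrix(stats::rnorm(n_states * n_classes, 0, noise_sd), n_states, n_classes)
  } else {
    prescribing <- matrix(stats::rnorm(n_states * n_classes), n_states, n_classes)
  }
  dimnames(prescribing) <- list(states, sprintf("class_%02d", seq_len(n_classes)))
  list(prescribing = prescribing, prevalence = prevalence)
}
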