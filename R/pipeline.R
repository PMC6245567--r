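## End-to-end orchestration: ingest -> profile -> embed -> cluster ->
## regional, with a JSON-lines manifest, plus figure rendering.

#' @importFrom rlang .data
NULL

#' Assemble a pipeline configuration
#'
#' All randomness downstream flows from the single `seed`; each
#' stochastic stage derives its own seed from it, so a rerun with the
#' same configuration reproduces every artifact byte for byte.
#'
#' @param simulation a [simulationConfig()] to generate synthetic input,
#'   or `NULL` when reading PUF files.
#' @param provider_file,drug_file,link_file PUF-shaped input tables (used
#'   when `simulation` is `NULL`).
#' @param censor_threshold small-cell censoring threshold.
#' @param min_claims provider volume floor for profile/embedding stages.
#' @param level feature level, `"drugs"` or `"classes"`.
#' @param pca_dims,perplexity,theta,max_iters,n_restarts embedding
#'   parameters (see [tsneEmbed()]).
#' @param cluster_k number of agglomerative clusters.
#' @param region_level `"cbsa"` or `"state"`.
#' @param min_national_claims strict feature filter for region profiles.
#' @param n_perm permutations for the regional null.
#' @param outdir output directory.
#' @param seed global integer seed.
#' @return config list of class `rx_pipeline_config`.
#' @export
pipelineConfig <- function(simulation = NULL, provider_file = NULL,
                           drug_file = NULL, link_file = NULL,
                           censor_threshold = 11, min_claims = 0,
                           level = c("drugs", "classes"),
                           pca_dims = 50, perplexity = 40, theta = 0.5,
                           max_iters = 500, n_restarts = 2, cluster_k = 20,
                           region_level = c("cbsa", "state"),
                           min_national_claims = 0, n_perm = 50,
                           outdir = tempfile("rxscape_run_"), seed = 1L) {
  cfg <- list(simulation = simulation, provider_file = provider_file,
              drug_file = drug_file, link_file = link_file,
              censor_threshold = censor_threshold, min_claims = min_claims,
              level = match.arg(level), pca_dims = pca_dims,
              perplexity = perplexity, theta = theta, max_iters = max_iters,
              n_restarts = n_restarts, cluster_k = cluster_k,
              region_level = match.arg(region_level),
              min_national_claims = min_national_claims, n_perm = n_perm,
              outdir = outdir, seed = as.integer(seed))
  class(cfg) <- "rx_pipeline_config"
  cfg
}

.manifest_record <- function(stage, status, params = list(), outputs = character()) {
  hashes <- if (length(outputs)) as.list(tools::md5sum(outputs)) else list()
  list(stage = stage, status = status, params = params,
       outputs = as.list(outputs), md5 = hashes)
}

#' Run the full analysis pipeline
#'
#' Executes ingest, profile, embedding, clustering and regional stages in
#' order, writing each stage's tabular outputs under `config$outdir` and
#' a JSON-lines manifest (`manifest.jsonl`) recording, per stage, its
#' status, parameters, output files and their MD5 hashes. A stage failure
#' is recorded in the manifest and later stages are skipped.
#'
#' @param config a [pipelineConfig()].
#' @return list with `results` (per-stage objects), `manifest`
#'   (list of records) and `manifest_path`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "rx_pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  failed <- FALSE
  add <- function(rec) manifest[[length(manifest) + 1]] <<- rec
  run_stage <- function(stage, params, fun) {
    if (failed) { add(.manifest_record(stage, "skipped")); return(invisible(NULL)) }
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      failed <<- TRUE
      add(c(.manifest_record(stage, "failed"), list(error = conditionMessage(out))))
      NULL
    } else {
      add(.manifest_record(stage, "complete", params, out$files))
      results[[stage]] <<- out
      out
    }
  }

  run_stage("ingest",
            list(censor_threshold = config$censor_threshold, seed = config$seed),
            function() {
    if (!is.null(config$simulation)) {
      pop <- generatePopulation(config$simulation)
      claims <- pop$claims
      if (config$censor_threshold != config$simulation$censor_threshold)
        claims <- applyCensoring(claims, config$censor_threshold)
      claims <- dropEmpty(claims)
      list(claims = claims, pop = pop, files = character())
    } else {
      claims <- readPuf(config$provider_file, config$drug_file,
                        config$link_file, config$censor_threshold)
      list(claims = claims, pop = NULL, files = character())
    }
  })

  run_stage("profile",
            list(level = config$level, min_claims = config$min_claims),
            function() {
    claims <- results$ingest$claims
    prof <- buildProfiles(claims, level = config$level, normalize = TRUE)
    prof <- filterMinClaims(prof, config$min_claims)
    if (nrow(profileValues(prof)) == 0)
      stop(sprintf("no provider has >= %s claims: empty cohort", config$min_claims))
    f <- file.path(config$outdir, "profiles.csv")
    utils::write.csv(data.frame(npi = rownames(profileValues(prof)),
                                total_claims = profileTotals(prof)),
                     f, row.names = FALSE)
    list(profiles = prof, files = f)
  })

  run_stage("embed",
            list(pca_dims = config$pca_dims, perplexity = config$perplexity,
                 theta = config$theta, max_iters = config$max_iters,
                 n_restarts = config$n_restarts, seed = config$seed),
            function() {
    prof <- results$profile$profiles
    red <- suppressWarnings(pcaReduce(prof, k = config$pca_dims))
    emb <- tsneEmbed(red, perplexity = config$perplexity, theta = config$theta,
                     max_iters = config$max_iters,
                     n_restarts = config$n_restarts, seed = config$seed)
    co <- embeddingCoords(emb)
    f <- file.path(config$outdir, "embedding.csv")
    utils::write.csv(data.frame(npi = rownames(co), x = co[, 1], y = co[, 2],
                                cost = embeddingCosts(emb)[emb@selected]),
                     f, row.names = FALSE)
    list(embedding = emb, reduced = red, files = f)
  })

  run_stage("cluster",
            list(k = config$cluster_k, linkage = "ward"),
            function() {
    prof <- results$profile$profiles
    cl <- wardCluster(prof, k = min(config$cluster_k, nrow(profileValues(prof))))
    f <- file.path(config$outdir, "clusters.csv")
    utils::write.csv(data.frame(npi = names(cl$cluster), cluster = cl$cluster),
                     f, row.names = FALSE)
    list(clustering = cl, files = f)
  })

  run_stage("regional",
            list(level = config$region_level, n_perm = config$n_perm,
                 min_national_claims = config$min_national_claims,
                 seed = config$seed),
            function() {
    claims <- results$ingest$claims
    regions <- providerRegions(claims, config$region_level)
    enr <- if (!is.null(results$ingest$pop)) results$ingest$pop$enrollees else {
      tab <- table(regions)
      stats::setNames(as.numeric(tab) * 40, names(tab))
    }
    rp <- regionProfiles(claims, regions, enr, config$min_national_claims)
    nul <- permutationNull(claims, regions, enr, n_perm = config$n_perm,
                           seed = config$seed + 1L,
                           min_national_claims = config$min_national_claims)
    f1 <- file.path(config$outdir, "region_rates.csv")
    utils::write.csv(as.data.frame(regionRates(rp)), f1)
    f2 <- file.path(config$outdir, "region_mds.csv")
    utils::write.csv(data.frame(region = rownames(nul$real_coords),
                                nul$real_coords), f2, row.names = FALSE)
    list(region_profiles = rp, null = nul, files = c(f1, f2))
  })

  path <- file.path(config$outdir, "manifest.jsonl")
  writeLines(vapply(manifest, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA)),
    character(1)), path)
  list(results = results, manifest = manifest, manifest_path = path)
}

#' Render the standard figure set
#'
#' Produces the package's figure panels from pipeline results: the 2-D
#' embedding density heatmap; a per-specialty highlight grid (one panel
#' per specialty, that specialty in red over the grey density); a
#' per-feature claim-fraction overlay on the capped percent scale; a
#' log-log region-pair scatter of claims per enrollee with dashed
#' fold-difference bands; and the region MDS scatter with the permuted
#' null cloud.
#'
#' @param run result of [runPipeline()].
#' @param which subset of `c("density", "specialty_grid", "fraction",
#'   "region_pair", "mds")`.
#' @param outdir output directory (default: the pipeline outdir contents'
#'   directory).
#' @param feature feature for the fraction overlay (default: highest
#'   national volume drug).
#' @param cap fraction-overlay cap in percent (default 15).
#' @param regions length-2 region labels for the pair scatter (default:
#'   first two regions).
#' @param fold fold band for the pair scatter (default 5).
#' @return named character vector of written image files.
#' @export
renderFigures <- function(run,
                          which = c("density", "specialty_grid", "fraction",
                                    "region_pair", "mds"),
                          outdir = dirname(run$manifest_path),
                          feature = NULL, cap = 15, regions = NULL, fold = 5) {
  which <- match.arg(which, several.ok = TRUE)
  res <- run$results
  need <- function(stage) {
    if (is.null(res[[stage]]))
      stop(sprintf("required artifact missing: rerun stage '%s'", stage),
           call. = FALSE)
    res[[stage]]
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  save_png <- function(p, name, width = 5, height = 4) {
    f <- file.path(outdir, paste0(name, ".png"))
    ggplot2::ggsave(f, p, width = width, height = height, dpi = 120)
    out[name] <<- f
  }

  if (any(c("density", "specialty_grid", "fraction") %in% which)) {
    emb <- need("embed")$embedding
    co <- as.data.frame(embeddingCoords(emb))
    names(co) <- c("x", "y")
    co$npi <- rownames(embeddingCoords(emb))
  }

  if ("density" %in% which) {
    p <- ggplot2::ggplot(co, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_bin2d(bins = 40) +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(title = "Provider density in the embedding",
                    x = "t-SNE 1", y = "t-SNE 2") +
      ggplot2::theme_minimal()
    save_png(p, "density")
  }

  if ("specialty_grid" %in% which) {
    claims <- need("ingest")$claims
    spec <- stats::setNames(colData(claims)$specialty_description, colnames(claims))
    co$specialty <- spec[co$npi]
    for (s in sort(unique(co$specialty))) {
      p <- ggplot2::ggplot(co, ggplot2::aes(x = .data$x, y = .data$y)) +
        ggplot2::geom_point(color = "grey70", size = 0.6) +
        ggplot2::geom_point(data = co[co$specialty == s, , drop = FALSE],
                            color = "red", size = 0.8) +
        ggplot2::labs(title = s, x = "t-SNE 1", y = "t-SNE 2") +
        ggplot2::theme_minimal()
      save_png(p, paste0("specialty_", gsub("[^A-Za-z0-9]+", "_", s)))
    }
  }

  if ("fraction" %in% which) {
    claims <- need("ingest")$claims
    if (is.null(feature))
      feature <- names(which.max(drugTotals(claims)))
    fr <- annotateFraction(claims, feature, level = "drugs", cap = cap)
    co$fraction <- fr[co$npi]
    p <- ggplot2::ggplot(co, ggplot2::aes(x = .data$x, y = .data$y,
                                          color = .data$fraction)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_color_gradient(low = "grey80", high = "red",
                                    limits = c(0, cap)) +
      ggplot2::labs(title = paste0(feature, " (% of claims, capped at ",
                                   cap, "%)"),
                    x = "t-SNE 1", y = "t-SNE 2", color = "%") +
      ggplot2::theme_minimal()
    save_png(p, "fraction")
  }

  if ("region_pair" %in% which) {
    rp <- need("regional")$region_profiles
    if (is.null(regions)) regions <- rownames(regionRates(rp))[1:2]
    cmp <- pairwiseRegionCompare(rp, regions[1], regions[2], fold = fold)
    p <- ggplot2::ggplot(cmp, ggplot2::aes(x = .data$rate_a, y = .data$rate_b,
                                           color = .data$flagged)) +
      ggplot2::geom_point(size = 1) +
      ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey50") +
      ggplot2::geom_abline(slope = 1, intercept = log10(fold),
                           linetype = "dashed") +
      ggplot2::geom_abline(slope = 1, intercept = -log10(fold),
                           linetype = "dashed") +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::scale_color_manual(values = c("FALSE" = "grey40",
                                             "TRUE" = "red")) +
      ggplot2::labs(x = paste(regions[1], "claims/enrollee"),
                    y = paste(regions[2], "claims/enrollee"),
                    title = sprintf("%s vs %s (%g-fold band)",
                                    regions[1], regions[2], fold)) +
      ggplot2::theme_minimal()
    save_png(p, "region_pair")
  }

  if ("mds" %in% which) {
    nul <- need("regional")$null
    real <- data.frame(nul$real_coords, region = rownames(nul$real_coords))
    names(real)[1:2] <- c("x", "y")
    perm <- as.data.frame(nul$perm_coords)
    names(perm)[1:2] <- c("x", "y")
    p <- ggplot2::ggplot(real, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point(data = perm, color = "magenta", size = 0.5,
                          alpha = 0.4) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_text(ggplot2::aes(label = .data$region), vjust = -0.8,
                         size = 3) +
      ggplot2::labs(title = "Region MDS with permutation null",
                    x = "MDS 1", y = "MDS 2") +
      ggplot2::theme_minimal()
    save_png(p, "mds")
  }
  out
}
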