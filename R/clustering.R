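## Ward agglomerative clustering of provider profiles and
## cluster-specialty dominance / cluster-region composition analyses.

#' Agglomerative clustering of provider profiles
#'
#' Hierarchical clustering of the providers-by-features matrix using
#' Euclidean distances and, by default, Ward's minimum-variance linkage
#' (each merge minimizes the increase in total within-cluster variance);
#' centroid linkage is available behind the `linkage` flag. The tree is
#' cut either at a requested cluster count `k` or at a merge height `h`.
#'
#' @param profile a [ProfileMatrix-class] or numeric matrix
#'   (rows = providers).
#' @param k number of clusters, or `NULL` to cut by height.
#' @param h merge-height cut (used when `k` is `NULL`).
#' @param linkage `"ward"` (hclust `ward.D2` on Euclidean distances) or
#'   `"centroid"` (on squared distances, heights back-transformed).
#' @return list of class `rx_clustering`: `cluster` (named integer
#'   assignment), `tree` (the `hclust` object), `k`, `linkage`,
#'   `metric`.
#' @export
wardCluster <- function(profile, k = NULL, h = NULL,
                        linkage = c("ward", "centroid")) {
  linkage <- match.arg(linkage)
  m <- if (is(profile, "ProfileMatrix")) profileValues(profile) else as.matrix(profile)
  n <- nrow(m)
  if (!is.null(k) && (k < 1 || k > n))
    stop(sprintf("k = %s outside 1..%d providers", format(k), n), call. = FALSE)
  if (is.null(k) && is.null(h))
    stop("either k or h must be given", call. = FALSE)
  d <- stats::dist(m)
  tree <- if (linkage == "ward") stats::hclust(d, method = "ward.D2")
          else stats::hclust(d^2, method = "centroid")
  cl <- if (!is.null(k)) stats::cutree(tree, k = k) else stats::cutree(tree, h = h)
  names(cl) <- rownames(m)
  structure(list(cluster = cl, tree = tree,
                 k = length(unique(cl)), linkage = linkage,
                 metric = "euclidean"),
            class = "rx_clustering")
}

#' @export
print.rx_clustering <- function(x, ...) {
  cat("Agglomerative clustering:", length(x$cluster), "providers,",
      x$k, "clusters;", x$linkage, "linkage,", x$metric, "metric\n")
  invisible(x)
}

#' Cluster-specialty dominance analysis
#'
#' For each cluster, the dominant (most frequent) provider specialty and
#' its fraction of the cluster; ties are broken lexicographically and
#' flagged. Summarised as the fraction of clusters whose dominant
#' specialty accounts for at least `threshold` of its providers, plus a
#' tally of second-most-frequent specialties over clusters with at least
#' two specialties.
#'
#' @param clustering result of [wardCluster()] or a named assignment
#'   vector.
#' @param specialties named specialty labels covering all providers.
#' @param threshold dominance threshold (default 0.30).
#' @return list with `per_cluster` data.frame (`cluster`, `size`,
#'   `dominant`, `fraction`, `tie`), `summary_fraction`, and
#'   `second_specialties` (table).
#' @export
clusterDominance <- function(clustering, specialties, threshold = 0.30) {
  cl <- if (inherits(clustering, "rx_clustering")) clustering$cluster else clustering
  stopifnot(!is.null(names(cl)))
  sp <- specialties[names(cl)]
  if (anyNA(sp)) stop("specialty labels do not cover all providers", call. = FALSE)
  ids <- sort(unique(cl))
  rows <- lapply(ids, function(g) {
    tab <- sort(table(sp[cl == g]), decreasing = TRUE)
    stopifnot(length(tab) > 0)     # empty clusters are impossible by construction
    top <- tab[tab == tab[1]]
    dominant <- sort(names(top))[1]
    second <- if (length(tab) >= 2) names(tab)[2] else NA_character_
    data.frame(cluster = g, size = sum(cl == g), dominant = dominant,
               fraction = as.numeric(tab[1]) / sum(tab),
               tie = length(top) > 1, second = second,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  multi <- !is.na(per$second)
  list(per_cluster = per[, c("cluster", "size", "dominant", "fraction", "tie")],
       summary_fraction = mean(per$fraction >= threshold),
       second_specialties = table(per$second[multi]))
}

#' Cluster-by-region composition table
#'
#' Tallies, per cluster, the proportion of providers in each geographic
#' region (US Federal Region, Census Region, or state), resolving regions
#' from two-letter state codes via the packaged lookup. Unknown state
#' codes fall in an `"unresolved"` bucket. Each row sums to 1.
#'
#' @param clustering result of [wardCluster()] or a named assignment
#'   vector.
#' @param states named two-letter state codes covering all providers.
#' @param level `"federal_region"`, `"census_region"`, or `"state"`.
#' @return clusters-by-regions proportion matrix.
#' @export
clusterRegionCross <- function(clustering, states,
                               level = c("federal_region", "census_region",
                                         "state")) {
  level <- match.arg(level)
  cl <- if (inherits(clustering, "rx_clustering")) clustering$cluster else clustering
  st <- states[names(cl)]
  reg <- if (level == "state") st else stateRegionLookup(st, level)
  reg[is.na(reg)] <- "unresolved"
  tab <- table(cluster = cl, region = reg)
  prop.table(tab, margin = 1)
}

## State -> region lookup (two-letter postal codes). Federal regions are
## the ten standard administrative (HHS/GSA) regions; census regions are
## the four Census Bureau regions (PR and territories have no census
## region and resolve to NA).
.federal_regions <- list(
  "Region 1"  = c("CT", "ME", "MA", "NH", "RI", "VT"),
  "Region 2"  = c("NJ", "NY", "PR", "VI"),
  "Region 3"  = c("DE", "DC", "MD", "PA", "VA", "WV"),
  "Region 4"  = c("AL", "FL", "GA", "KY", "MS", "NC", "SC", "TN"),
  "Region 5"  = c("IL", "IN", "MI", "MN", "OH", "WI"),
  "Region 6"  = c("AR", "LA", "NM", "OK", "TX"),
  "Region 7"  = c("IA", "KS", "MO", "NE"),
  "Region 8"  = c("CO", "MT", "ND", "SD", "UT", "WY"),
  "Region 9"  = c("AZ", "CA", "HI", "NV", "AS", "GU", "MP"),
  "Region 10" = c("AK", "ID", "OR", "WA"))

.census_regions <- list(
  Northeast = c("CT", "ME", "MA", "NH", "RI", "VT", "NJ", "NY", "PA"),
  Midwest   = c("IL", "IN", "MI", "OH", "WI", "IA", "KS", "MN", "MO",
                "NE", "ND", "SD"),
  South     = c("DE", "DC", "FL", "GA", "MD", "NC", "SC", "VA", "WV",
                "AL", "KY", "MS", "TN", "AR", "LA", "OK", "TX"),
  West      = c("AZ", "CO", "ID", "MT", "NV", "NM", "UT", "WY", "AK",
                "CA", "HI", "OR", "WA"))

#' Resolve state codes to US regions
#'
#' @param states character vector of two-letter state/territory codes.
#' @param level `"federal_region"` or `"census_region"`.
#' @return character vector of region labels (`NA` for unknown codes).
#' @export
stateRegionLookup <- function(states, level = c("federal_region",
                                                "census_region")) {
  level <- match.arg(level)
  tab <- if (level == "federal_region") .federal_regions else .census_regions
  map <- rep(names(tab), lengths(tab))
  names(map) <- unlist(tab)
  unname(map[states])
}
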