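## PCA pre-processing and exact t-SNE embedding with min-cost restart
## selection, plus density maps and annotation layers.

#' PCA reduction of a profile matrix
#'
#' Projects providers onto the top-`k` principal components of the
#' centered composition matrix (no additional variance scaling: the only
#' normalization is by provider totals). When `k` exceeds the matrix
#' rank, the rank number of components is retained with a warning.
#'
#' @param profile a [ProfileMatrix-class] or a plain numeric matrix
#'   (rows = providers).
#' @param k number of components (default 50).
#' @return scores matrix (providers x components) with attribute `sdev`
#'   (component standard deviations, non-increasing).
#' @export
pcaReduce <- function(profile, k = 50) {
  m <- if (is(profile, "ProfileMatrix")) profileValues(profile) else as.matrix(profile)
  k0 <- min(k, dim(m))
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = k0)
  rank_eff <- sum(pc$sdev > pc$sdev[1] * 1e-9)
  if (k > rank_eff) {
    warning(sprintf("k = %d exceeds matrix rank %d; retaining %d components",
                    k, rank_eff, rank_eff))
    k0 <- rank_eff
  }
  out <- pc$x[, seq_len(min(k0, ncol(pc$x))), drop = FALSE]
  attr(out, "sdev") <- pc$sdev[seq_len(ncol(out))]
  attr(out, "rotation") <- pc$rotation[, seq_len(ncol(out)), drop = FALSE]
  out
}

## ---- exact t-SNE engine ----------------------------------------------

## Conditional -> joint affinities with per-point precision found by
## binary search on the Shannon entropy (log perplexity).
.tsne_affinities <- function(X, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D[D < 0] <- 0
  diag(D) <- 0
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1; betamin <- -Inf; betamax <- Inf
    for (tr in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else { betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    pi <- exp(-di * beta)
    pi <- pi / sum(pi)
    P[i, -i] <- pi
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

.tsne_run <- function(X, perplexity, max_iters, seed,
                      eta = 200, exaggeration = 12) {
  n <- nrow(X)
  P <- .tsne_affinities(X, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  stop_lying <- min(100, floor(max_iters / 3))
  mom_switch <- min(250, floor(max_iters / 2))
  Pe <- P * exaggeration
  for (it in seq_len(max_iters)) {
    Pit <- if (it <= stop_lying) Pe else P
    sq <- rowSums(Y^2)
    W <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    M <- (Pit - Q) * W
    grad <- 4 * (rowSums(M) * Y - M %*% Y)
    momentum <- if (it <= mom_switch) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  sq <- rowSums(Y^2)
  W <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
  diag(W) <- 0
  Q <- pmax(W / sum(W), 1e-12)
  cost <- sum(P * log(P / Q))
  list(Y = Y, cost = cost)
}

#' t-SNE embedding with min-cost restart selection
#'
#' Embeds providers in two dimensions by t-distributed stochastic
#' neighbor embedding with the exact gradient (Euclidean affinities on
#' the PCA-reduced compositions, per-point perplexity calibration, early
#' exaggeration, adaptive gains). The optimisation is restarted
#' `n_restarts` times from seeds derived from `seed`, and the run with
#' the minimum final Kullback-Leibler cost is returned; identical seeds
#' and parameters give bit-identical coordinates.
#'
#' @param X numeric matrix of points (rows = providers), typically the
#'   output of [pcaReduce()].
#' @param perplexity effective neighbor count (default 40); must satisfy
#'   `perplexity < (n - 1) / 3`.
#' @param theta Barnes-Hut accuracy parameter in `[0, 1]`, accepted for
#'   interface compatibility; the exact gradient is used at these scales.
#' @param max_iters gradient iterations per run, in `[300, 1500]`.
#' @param n_restarts independent restarts (default 5).
#' @param seed integer seed from which per-run seeds are derived.
#' @return an [Embedding2D-class].
#' @export
tsneEmbed <- function(X, perplexity = 40, theta = 0.5, max_iters = 1000,
                      n_restarts = 5, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("t-SNE requires at least 10 points", call. = FALSE)
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]", call. = FALSE)
  if (max_iters < 300 || max_iters > 1500)
    stop("max_iters must lie in [300, 1500]", call. = FALSE)
  if (perplexity >= (n - 1) / 3)
    stop(sprintf("perplexity %s infeasible for n = %d; must be < %.2f",
                 format(perplexity), n, (n - 1) / 3), call. = FALSE)
  runs <- lapply(seq_len(n_restarts), function(r)
    .tsne_run(X, perplexity, max_iters, seed = as.integer(seed) + r - 1L))
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  sel <- which.min(costs)
  coords <- runs[[sel]]$Y
  rownames(coords) <- rownames(X)
  colnames(coords) <- c("tsne1", "tsne2")
  new("Embedding2D", coords = coords, costs = costs, selected = as.integer(sel),
      params = list(perplexity = perplexity, theta = theta,
                    max_iters = max_iters, n_restarts = n_restarts,
                    seed = as.integer(seed)))
}

#' 2-D histogram of embedding density
#'
#' Bins the embedding coordinates on a regular grid; counts sum to the
#' number of providers in the subset. The grid is fixed by the full
#' embedding's range so subset maps are additive.
#'
#' @param embedding an [Embedding2D-class].
#' @param bins bins per axis (>= 2).
#' @param subset logical/character/integer provider subset, or `NULL`.
#' @return `bins x bins` count matrix with attributes `xbreaks`/`ybreaks`.
#' @export
densityMap <- function(embedding, bins = 50, subset = NULL) {
  if (bins < 2) stop("bins must be >= 2 per axis", call. = FALSE)
  co <- embeddingCoords(embedding)
  xb <- seq(min(co[, 1]), max(co[, 1]), length.out = bins + 1)
  yb <- seq(min(co[, 2]), max(co[, 2]), length.out = bins + 1)
  if (!is.null(subset)) co <- co[subset, , drop = FALSE]
  h <- matrix(0L, bins, bins)
  if (nrow(co) == 0) {
    warning("empty subset: density map is all zero")
  } else {
    ix <- pmin(pmax(findInterval(co[, 1], xb, all.inside = TRUE), 1L), bins)
    iy <- pmin(pmax(findInterval(co[, 2], yb, all.inside = TRUE), 1L), bins)
    for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1L
  }
  attr(h, "xbreaks") <- xb; attr(h, "ybreaks") <- yb
  h
}

#' Per-provider claim fraction for one drug or class, capped for display
#'
#' Computes the percentage of each provider's claims going to one feature
#' (drug or class), clipped at `cap` percent -- the annotation-layer
#' convention where the color scale saturates at the cap. Zero-total
#' providers get 0 and are flagged.
#'
#' @param x a [ClaimsExperiment-class].
#' @param feature drug key or class label.
#' @param level `"drugs"` or `"classes"`.
#' @param classMap optional drug -> class map (defaults to `rowData(x)$class`).
#' @param cap clipping cap in percent (default 15).
#' @return named numeric vector (percent, clipped); attribute
#'   `zero_total` marks providers with no claims.
#' @export
annotateFraction <- function(x, feature, level = c("drugs", "classes"),
                             classMap = NULL, cap = 15) {
  level <- match.arg(level)
  cnt <- claimCounts(x)
  totals <- Matrix::colSums(cnt)
  if (level == "drugs") {
    if (!feature %in% rownames(cnt))
      stop(sprintf("drug '%s' not found in the claims matrix", feature), call. = FALSE)
    f <- as.numeric(cnt[feature, ])
  } else {
    cls <- if (is.null(classMap)) rowData(x)$class else
      classMap$class[match(rownames(cnt), classMap$drug_key)]
    if (is.null(cls)) stop("no class labels available", call. = FALSE)
    if (!feature %in% cls)
      stop(sprintf("class '%s' not found", feature), call. = FALSE)
    f <- Matrix::colSums(cnt[cls == feature, , drop = FALSE])
  }
  zero <- totals == 0
  val <- numeric(length(totals))
  val[!zero] <- 100 * f[!zero] / totals[!zero]
  val <- pmin(val, cap)
  names(val) <- colnames(cnt)
  attr(val, "zero_total") <- zero
  val
}

#' k-nearest-neighbor label purity of an embedding
#'
#' For each point, the fraction of its `k` nearest neighbors (Euclidean,
#' in the given coordinates) sharing its label; returns the mean over
#' points. Used to quantify how well an embedding separates planted or
#' annotated groups.
#'
#' @param coords numeric matrix of coordinates (rows = points) or an
#'   [Embedding2D-class].
#' @param labels vector of group labels, one per point.
#' @param k neighbors per point (default 15).
#' @return mean purity in `[0, 1]`.
#' @export
knnPurity <- function(coords, labels, k = 15) {
  if (is(coords, "Embedding2D")) coords <- embeddingCoords(coords)
  n <- nrow(coords)
  stopifnot(length(labels) == n, k < n)
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  mean(vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    mean(labels[nb] == labels[i])
  }, numeric(1)))
}
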