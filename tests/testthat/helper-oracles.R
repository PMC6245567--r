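# Independent oracles used to cross-check the package implementations.

# Gini as the mean absolute difference over all ordered pairs / (2 * mu).
gini_mad_oracle <- function(x) {
  mean(abs(outer(x, x, "-"))) / (2 * mean(x))
}

# Naive Ward agglomeration via the Lance-Williams recurrence on squared
# Euclidean distances; returns the partition at every cluster count.
ward_lw_oracle <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))^2
  diag(D) <- Inf
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  partitions <- list()
  assign_of <- function() {
    cl <- integer(n)
    for (g in which(active)) cl[members[[g]]] <- g
    cl
  }
  partitions[[n]] <- assign_of()
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    i <- idx[min(k)]; j <- idx[max(k)]
    for (h in setdiff(which(active), c(i, j))) {
      D[i, h] <- D[h, i] <-
        ((sizes[i] + sizes[h]) * D[i, h] + (sizes[j] + sizes[h]) * D[j, h] -
           sizes[h] * D[i, j]) / (sizes[i] + sizes[j] + sizes[h])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    D[j, ] <- D[, j] <- Inf
    partitions[[n - step]] <- assign_of()
  }
  partitions
}

# TRUE when two cluster assignments define the same partition.
same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# Exact two-sided Mann-Whitney p-value by enumerating all group
# assignments of the combined sample (no ties assumed).
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  U_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- U_stat(a, b)
  combos <- combn(length(pooled), n1)
  us <- apply(combos, 2, function(ix) U_stat(pooled[ix], pooled[-ix]))
  mu <- n1 * (length(b)) / 2
  min(1, mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# Adjusted Rand index (used when mclust is unavailable).
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

adj_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    mclust::adjustedRandIndex(a, b)
  else ari_oracle(a, b)
}
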