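region_fixture <- function(effect_sd = 0, n = 240, seed = 27) {
  cfg <- simulationConfig(
    n_providers = n, n_drugs = 50, n_classes = 10,
    specialties = specialtySpecs(50, 2),
    regions = regionSpecs(3, effect_sd = effect_sd), seed = seed)
  generatePopulation(cfg)
}

test_that("region profiles are claims per enrollee with a strict filter", {
  m <- matrix(500, 1, 1, dimnames = list("A|a", "p1"))
  x <- tiny_claims(m)
  rp <- regionProfiles(x, c(p1 = "R1"), c(R1 = 100))
  expect_equal(unname(regionRates(rp)["R1", "A|a"]), 5)
  expect_error(regionProfiles(x, c(p1 = "R1"), c(R1 = 100),
                              min_national_claims = 500), "no feature")
  expect_warning(regionProfiles(x, c(p1 = "R1"), c(R2 = 10)), "enrollee")
})

test_that("per-region sums match a brute-force group-by", {
  pop <- region_fixture()
  regions <- pop$truth$region
  rp <- regionProfiles(pop$claims, regions, pop$enrollees)
  cnt <- as.matrix(claimCounts(pop$claims))
  for (r in rownames(regionRates(rp))) {
    brute <- rowSums(cnt[, names(regions)[regions == r], drop = FALSE])
    brute <- brute[colnames(regionRates(rp))] / pop$enrollees[r]
    expect_equal(regionRates(rp)[r, ], brute, ignore_attr = TRUE)
  }
})

test_that("correlation distance matches hand-computed cases", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  d <- correlationDistance(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  m2 <- rbind(a = c(1, 0, 0), b = c(0, 1, 0))
  expect_equal(correlationDistance(m2)["a", "b"], 1.5)
  expect_error(correlationDistance(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance.*a")
})

test_that("correlation distance is a valid bounded semi-metric", {
  set.seed(29)
  for (rep in 1:20) {
    m <- matrix(rlnorm(6 * 15), 6, 15,
                dimnames = list(paste0("r", 1:6), NULL))
    d <- correlationDistance(m)
    expect_equal(unname(diag(d)), rep(0, 6))
    expect_equal(d, t(d), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(d >= 0 & d <= 2))
  }
})

test_that("classical MDS recovers Euclidean configurations", {
  # 3-4-5 right triangle
  D <- rbind(c(0, 3, 4), c(3, 0, 5), c(4, 5, 0))
  rownames(D) <- colnames(D) <- c("a", "b", "c")
  pts <- classicalMds(D, k = 2)
  expect_equal(as.matrix(dist(pts)), D, tolerance = 1e-9, ignore_attr = TRUE)

  # general Euclidean point sets, recovered to numerical tolerance
  set.seed(30)
  for (rep in 1:10) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    D2 <- as.matrix(dist(X))
    pts2 <- classicalMds(D2, k = 3)
    expect_equal(as.matrix(dist(pts2)), D2, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }

  # all-equal off-diagonal distances: equilateral configuration
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  p3 <- suppressWarnings(classicalMds(D3, k = 2))
  pd <- as.numeric(dist(p3))
  expect_equal(max(pd) - min(pd), 0, tolerance = 1e-9)
})

test_that("MDS is equivariant under region permutation", {
  set.seed(31)
  X <- matrix(rnorm(7 * 3), 7, 3)
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- paste0("r", 1:7)
  ord <- sample(7)
  a <- classicalMds(D, 2)
  b <- classicalMds(D[ord, ord], 2)[rownames(D), ]
  expect_equal(as.matrix(dist(a)), as.matrix(dist(b)), tolerance = 1e-9)
})

test_that("permutations preserve per-region counts and total claims", {
  pop <- region_fixture()
  regions <- pop$truth$region
  out <- permutationNull(pop$claims, regions, pop$enrollees, n_perm = 3,
                         seed = 1)
  expect_identical(nrow(out$perm_coords), 3L * nrow(out$real_coords))
  # the permutation machinery never changes total claims
  total <- sum(regionRates(regionProfiles(pop$claims, regions,
                                          pop$enrollees)) *
                 as.numeric(pop$enrollees[rownames(out$real_coords)]))
  expect_equal(total, sum(claimCounts(pop$claims)))
  # label shuffling preserves counts by construction
  set.seed(2)
  shuffled <- regions
  shuffled[] <- regions[sample(length(regions))]
  regs <- sort(unique(regions))
  expect_equal(as.vector(table(shuffled)[regs]),
               as.vector(table(regions)[regs]))
  expect_error(permutationNull(pop$claims, regions, pop$enrollees,
                               n_perm = 0), "n_perm")
})

test_that("a planted regional effect exceeds the permutation null", {
  pop <- region_fixture(effect_sd = 0.8)
  out <- permutationNull(pop$claims, pop$truth$region, pop$enrollees,
                         n_perm = 59, seed = 1)
  expect_gt(out$real_dispersion, quantile(out$perm_dispersions, 0.95))
  expect_gte(out$percentile, 0.95)
})

test_that("without regional effects the real dispersion is typical of the null", {
  pop <- region_fixture(effect_sd = 0, seed = 28)
  out <- suppressWarnings(
    permutationNull(pop$claims, pop$truth$region, pop$enrollees,
                    n_perm = 99, seed = 1))
  expect_gte(out$percentile, 0.025)
  expect_lte(out$percentile, 0.975)
})

test_that("pairwise region comparison flags fold-band outliers", {
  rates <- rbind(R1 = c(10, 10, 8, 0.5), R2 = c(1, 10, 2, 0))
  colnames(rates) <- paste0("f", 1:4)
  rp <- new("RegionProfiles", rates = rates, enrollees = c(R1 = 1, R2 = 1),
            minNationalClaims = 0)
  cmp <- pairwiseRegionCompare(rp, "R1", "R2", fold = 5)
  expect_identical(cmp$feature, c("f1", "f2", "f3"))   # zero-rate f4 excluded
  expect_identical(cmp$flagged, c(TRUE, FALSE, FALSE))
  cmp2 <- pairwiseRegionCompare(rp, "R1", "R2", fold = 5,
                                zero_handling = "pseudocount")
  expect_identical(nrow(cmp2), 4L)
  expect_true(cmp2$flagged[4])
  expect_error(pairwiseRegionCompare(rp, "R1", "XX"), "unknown region")
})

test_that("a planted 8-fold effect is exactly the feature flagged", {
  set.seed(35)
  base <- rlnorm(20, 0, 0.05)
  rates <- rbind(R1 = base, R2 = base)
  rates[2, 7] <- rates[2, 7] * 8
  colnames(rates) <- paste0("f", 1:20)
  rp <- new("RegionProfiles", rates = rates, enrollees = c(R1 = 1, R2 = 1),
            minNationalClaims = 0)
  cmp <- pairwiseRegionCompare(rp, "R1", "R2", fold = 5)
  expect_identical(cmp$feature[cmp$flagged], "f7")
})

test_that("distance correlation: affine link gives R^2 = 1, and the 3-state
           case matches the closed form", {
  # a similarity map (scaling + duplication + shift) preserves distance
  # ratios exactly, so the two distance matrices correlate perfectly
  set.seed(3)
  prev <- matrix(rnorm(24), 8, 3, dimnames = list(paste0("S", 1:8), NULL))
  presc <- 3.7 * cbind(prev, prev) + 5
  rownames(presc) <- rownames(prev)
  expect_equal(stateDistanceCorrelation(presc, prev)$r_squared, 1,
               tolerance = 1e-9)

  # hand-checkable 3-state configuration
  p1 <- rbind(A = c(0, 0), B = c(1, 0), C = c(0, 2))
  p2 <- rbind(A = c(0, 0), B = c(2, 0), C = c(1, 1))
  got <- stateDistanceCorrelation(p1, p2)
  v1 <- as.numeric(dist(p1)); v2 <- as.numeric(dist(p2))
  expect_equal(got$r_squared, cor(v1, v2)^2, tolerance = 1e-12)

  expect_error(stateDistanceCorrelation(p1[1:2, ], p2[1:2, ]), "3 states")
  same <- rbind(A = c(1, 1), B = c(1, 1), C = c(1, 1))
  expect_error(stateDistanceCorrelation(p1, same), "zero variance")
})

test_that("distance correlation R^2 is scale-invariant and near zero for
           independent domains", {
  sp <- simulateStateProfiles(30, link = "independent", seed = 4)
  out <- stateDistanceCorrelation(sp$prescribing, sp$prevalence)
  expect_lt(out$r_squared, 0.1)
  scaled <- stateDistanceCorrelation(sp$prescribing * 100,
                                     sp$prevalence * 0.01)
  expect_equal(scaled$r_squared, out$r_squared, tolerance = 1e-12)
})

test_that("Mann-Whitney comparison uses exact small-sample enumeration", {
  out <- compareRegionFractions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(out$U), 0)
  expect_equal(out$p_value, 0.1)
  expect_true(out$exact)

  tie <- compareRegionFractions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tie$p_value, 1)

  set.seed(36)
  for (rep in 1:15) {
    a <- round(runif(sample(3:8, 1)), 3)
    b <- round(runif(sample(3:8, 1)), 3)
    if (anyDuplicated(c(a, b))) next
    got <- compareRegionFractions(a, b)
    expect_equal(got$p_value, mw_exact_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(compareRegionFractions(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney type-I error is near nominal under the null", {
  set.seed(37)
  rej <- mean(replicate(800, {
    compareRegionFractions(rnorm(30), rnorm(30))$p_value < 0.05
  }))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.075)
})
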