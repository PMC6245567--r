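test_that("normalization and class aggregation follow the compositional rules", {
  m <- matrix(c(11, 0, 33), 3, 1,
              dimnames = list(c("A|a", "B|b", "C|c"), "p1"))
  x <- tiny_claims(m, classes = c("K1", "K1", "K2"))
  prof <- buildProfiles(x, "drugs")
  expect_equal(unname(profileValues(prof)["p1", ]), c(0.25, 0, 0.75))

  # two drugs mapped to one class: counts add before normalization
  m2 <- matrix(c(11, 12, 20), 3, 1,
               dimnames = list(c("A|a", "B|b", "C|c"), "p1"))
  x2 <- tiny_claims(m2, classes = c("K1", "K1", "K2"))
  raw <- buildProfiles(x2, "classes", normalize = FALSE)
  expect_equal(unname(profileValues(raw)["p1", "K1"]), 23)

  # unmapped drugs are listed in the error
  bad_map <- data.frame(drug_key = c("A|a", "B|b"), class = "K1")
  expect_error(buildProfiles(x2, "classes", classMap = bad_map), "C\\|c")
})

test_that("class aggregation conserves provider totals", {
  pop <- small_pop()
  d <- buildProfiles(pop$claims, "drugs", normalize = FALSE)
  k <- buildProfiles(pop$claims, "classes", normalize = FALSE)
  expect_equal(rowSums(profileValues(d)), rowSums(profileValues(k)))
  expect_equal(unname(rowSums(profileValues(k))),
               unname(providerTotals(pop$claims)))
})

test_that("minimum-claims filter keeps the boundary provider", {
  m <- matrix(c(999, 1000, 1001), 1, 3,
              dimnames = list("A|a", c("p1", "p2", "p3")))
  prof <- buildProfiles(tiny_claims(m), "drugs")
  expect_identical(rownames(profileValues(filterMinClaims(prof, 1000))),
                   c("p2", "p3"))
  expect_identical(dim(profileValues(filterMinClaims(prof, 0))),
                   dim(profileValues(prof)))
  pop <- small_pop()
  p <- buildProfiles(pop$claims, "drugs")
  thr <- median(profileTotals(p))
  expect_identical(nrow(profileValues(filterMinClaims(p, thr))),
                   sum(providerTotals(pop$claims) >= thr))
})

test_that("diversity and reach summaries match direct scans", {
  m <- matrix(0, 3, 4, dimnames = list(c("A|a", "B|b", "C|c"), NULL))
  m[, 1] <- c(11, 40, 0)
  m[1, 2:3] <- 12
  x <- tiny_claims(m)
  dv <- diversityVolume(x)
  expect_equal(dv$providers$unique_drugs[1], 2)
  expect_equal(dv$providers$total_claims[1], 51)
  expect_equal(dv$drugs$prescriber_fraction[1], 100 * 3 / 4)

  pop <- small_pop()
  dv2 <- diversityVolume(pop$claims)
  cnt <- as.matrix(claimCounts(pop$claims))
  brute <- 100 * apply(cnt, 1, function(r) mean(r != 0))
  expect_equal(dv2$drugs$prescriber_fraction, unname(brute))
  expect_equal(mean(dv2$drugs$prescriber_fraction >= 5),
               mean(brute >= 5))
})

test_that("threshold summaries reproduce reported-share arithmetic", {
  expect_equal(shareMeeting(165, 2892), 5.7)
  expect_equal(shareMeeting(72, 197), 36.5)
  expect_equal(shareMeeting(0, 10), 0)
  expect_error(shareMeeting(1, 0), "feature_total")
  vals <- c(1, 2, 5, 10, 10)
  s <- thresholdSummary(vals, 5)
  expect_identical(s$count_meeting, 3L)
  expect_equal(s$percent, 60)
  # monotone non-increasing in the threshold
  pcts <- sapply(0:11, function(t) thresholdSummary(vals, t)$percent)
  expect_true(all(diff(pcts) <= 0))
})

test_that("Gini matches the mean-absolute-difference oracle", {
  expect_equal(giniIndex(rep(7, 10), bootstrap_reps = 0)$gini, 0)
  expect_equal(giniIndex(c(1, 2, 3, 4), bootstrap_reps = 0)$gini, 0.25)
  expect_equal(giniIndex(c(0, 0, 0, 10), bootstrap_reps = 0)$gini, 0.75)
  expect_error(giniIndex(c(0, 0)), "zero")
  expect_error(giniIndex(c(-1, 2)), "non-negative")
  set.seed(4)
  for (rep in 1:100) {
    v <- rlnorm(sample(3:40, 1), sd = sample(c(0.2, 1, 2), 1))
    expect_equal(giniIndex(v, bootstrap_reps = 0)$gini, gini_mad_oracle(v),
                 tolerance = 1e-12)
  }
})

test_that("Gini is scale-invariant and its bootstrap CI brackets the point", {
  set.seed(5)
  v <- rlnorm(200, sd = 1.2)
  g1 <- giniIndex(v, bootstrap_reps = 0)$gini
  expect_equal(giniIndex(17.3 * v, bootstrap_reps = 0)$gini, g1,
               tolerance = 1e-12)
  rep <- giniIndex(v, bootstrap_reps = 300, seed = 8)
  expect_true(rep$ci[1] <= rep$gini && rep$gini <= rep$ci[2])
  expect_true(rep$ci[1] >= 0 && rep$ci[2] <= 1)
})

test_that("cohort split respects the boundary and flags empty cohorts", {
  m <- matrix(c(24999, 25000), 1, 2,
              dimnames = list("A|a", c("p1", "p2")))
  x <- tiny_claims(m)
  out <- splitCohorts(x, totals = c(24999, 25000))
  expect_identical(out$hv, "p2")
  expect_identical(out$sv, "p1")
  expect_warning(splitCohorts(x, hv_threshold = 1, totals = c(24999, 25000)),
                 "empty")
})

test_that("a high-volume specialty is enriched in the HV cohort", {
  cfg <- simulationConfig(
    n_providers = 400, n_drugs = 60, n_classes = 10,
    specialties = specialtySpecs(60, 2, volume_scale = c(10, 1)),
    regions = regionSpecs(1), seed = 19)
  pop <- generatePopulation(cfg)
  thr <- stats::quantile(pop$truth$volumes, 0.9)
  out <- splitCohorts(pop$claims, hv_threshold = thr)
  comp <- out$composition
  expect_gt(comp["Specialty_01", "HV"], comp["Specialty_01", "SV"])
  expect_lt(out$p_value, 0.001)
})

test_that("state shares recover exact proportionality and match OLS", {
  states <- c("NY", "TX", "CA", "FL")
  n_prov <- c(10, 20, 30, 40)
  m <- matrix(12, 1, 100, dimnames = list("A|a", NULL))
  x <- tiny_claims(m, states = rep(states, n_prov))
  enr <- data.frame(state = states, enrollees = n_prov * 1000)
  out <- suppressWarnings(stateShares(x, enr))  # lm warns on a perfect fit
  expect_equal(out$slope, 1, tolerance = 1e-9)
  expect_equal(out$r_squared, 1, tolerance = 1e-9)
  expect_equal(sum(out$shares$provider_share), 100)
  expect_equal(sum(out$shares$enrollee_share), 100)

  # with noise, R^2 equals the squared Pearson correlation
  set.seed(23)
  enr2 <- data.frame(state = states, enrollees = n_prov * 1000 +
                       round(runif(4, 0, 9000)))
  out2 <- stateShares(x, enr2)
  expect_equal(out2$r_squared,
               cor(out2$shares$provider_share, out2$shares$enrollee_share)^2)

  expect_error(stateShares(x, data.frame(state = states, enrollees = 0)),
               "zero")
  x1 <- tiny_claims(m[, 1:5, drop = FALSE], states = rep("NY", 5))
  expect_warning(deg <- stateShares(x1, data.frame(state = "NY",
                                                   enrollees = 10)),
                 "degenerate")
  expect_true(deg$degenerate)
  expect_equal(deg$shares$provider_share, 100)
})
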