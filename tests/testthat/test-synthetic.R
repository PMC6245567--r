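test_that("uncensored generation conserves drawn volumes", {
  cfg <- simulationConfig(n_providers = 40, n_drugs = 30, n_classes = 5,
                          specialties = specialtySpecs(30, 1),
                          regions = regionSpecs(1), censor_threshold = 0,
                          seed = 3)
  pop <- generatePopulation(cfg)
  expect_equal(unname(providerTotals(pop$claims)),
               unname(pop$truth$volumes))
  expect_identical(censorThreshold(pop$claims), 0)
})

test_that("generation is deterministic in the seed", {
  cfg1 <- simulationConfig(n_providers = 30, n_drugs = 20, n_classes = 4,
                           seed = 11)
  cfg2 <- simulationConfig(n_providers = 30, n_drugs = 20, n_classes = 4,
                           seed = 12)
  a <- generatePopulation(cfg1)
  b <- generatePopulation(cfg1)
  c <- generatePopulation(cfg2)
  expect_identical(as.matrix(claimCounts(a$claims)),
                   as.matrix(claimCounts(b$claims)))
  expect_false(identical(as.matrix(claimCounts(a$claims)),
                         as.matrix(claimCounts(c$claims))))
})

test_that("config validation names the offending field", {
  expect_error(simulationConfig(n_providers = -5), "n_providers")
  bad_spec <- specialtySpecs(20, 2)
  bad_spec[[1]]$weight <- 0.9
  expect_error(simulationConfig(n_drugs = 20, n_classes = 5,
                                specialties = bad_spec),
               "specialties")
  bad_reg <- regionSpecs(2)
  bad_reg[[1]]$share <- 0.9
  expect_error(simulationConfig(regions = bad_reg), "regions")
  expect_error(simulationConfig(censor_threshold = -1), "censor_threshold")
  expect_error(simulationConfig(mixed_fraction = 1.5), "mixed_fraction")
})

test_that("well-separated specialties separate in composition space", {
  cfg <- simulationConfig(
    n_providers = 120, n_drugs = 40, n_classes = 8,
    specialties = specialtySpecs(40, 2, block_share = 1 - 1e-9),
    regions = regionSpecs(1), censor_threshold = 0, mixed_fraction = 0,
    seed = 5)
  pop <- generatePopulation(cfg)
  prof <- profileValues(buildProfiles(pop$claims, "drugs"))
  lab <- pop$truth$specialty[rownames(prof)]
  cs <- prof / sqrt(rowSums(prof^2))
  cosd <- 1 - tcrossprod(cs)
  same <- outer(lab, lab, "==")
  ut <- upper.tri(cosd)
  expect_gt(mean(cosd[!same & ut]), mean(cosd[same & ut]))
})

test_that("every drug belongs to exactly one class in the class map", {
  pop <- small_pop()
  expect_setequal(pop$classMap$drug_key, rownames(pop$claims))
  expect_false(anyDuplicated(pop$classMap$drug_key) > 0)
  expect_length(unique(pop$classMap$class), 20)
})

test_that("PUF tables round-trip losslessly on censored data", {
  pop <- small_pop()
  claims <- dropEmpty(pop$claims)
  dir <- withr::local_tempdir()
  paths <- writePufTables(claims, dir)
  back <- readPuf(paths["provider"], paths["drug"], paths["link"],
                  censor_threshold = censorThreshold(claims),
                  keep_empty = TRUE)
  expect_identical(dim(back), dim(claims))
  expect_equal(as.matrix(claimCounts(back))[rownames(claims), colnames(claims)],
               as.matrix(claimCounts(claims)))
})

test_that("the long table has one row per surviving non-zero cell", {
  pop <- small_pop()
  dir <- withr::local_tempdir()
  paths <- writePufTables(pop$claims, dir)
  link <- read.csv(paths["link"], colClasses = "character")
  expect_identical(nrow(link), sum(claimCounts(pop$claims) != 0))
})

test_that("an empty provider set writes headers-only tables", {
  pop <- small_pop()
  no_providers <- pop$claims[, integer(0)]
  dir <- withr::local_tempdir()
  paths <- writePufTables(no_providers, dir)
  expect_identical(length(readLines(paths["provider"])), 1L)
  expect_identical(length(readLines(paths["link"])), 1L)
  fully_empty <- pop$claims[integer(0), integer(0)]
  paths2 <- writePufTables(fully_empty, withr::local_tempdir())
  for (p in paths2) expect_identical(length(readLines(p)), 1L)
})

test_that("uncensored long-table column sums match ground-truth drug totals", {
  cfg <- simulationConfig(n_providers = 50, n_drugs = 25, n_classes = 5,
                          censor_threshold = 0, seed = 9)
  pop <- generatePopulation(cfg)
  dir <- withr::local_tempdir()
  paths <- writePufTables(pop$claims, dir)
  link <- read.csv(paths["link"])
  key <- paste(link$drug_name, link$generic_name, sep = "|")
  by_drug <- tapply(link$total_claim_count, key, sum)
  truth <- Matrix::rowSums(pop$truth$uncensored)
  expect_equal(by_drug[names(truth)[truth > 0]],
               truth[truth > 0], ignore_attr = TRUE)
})

test_that("raising the censor threshold never increases any cell", {
  cfg <- simulationConfig(n_providers = 60, n_drugs = 30, n_classes = 6,
                          censor_threshold = 0, seed = 21)
  pop <- generatePopulation(cfg)
  prev <- as.matrix(claimCounts(pop$claims))
  for (thr in c(2, 5, 11, 20)) {
    cur <- as.matrix(claimCounts(applyCensoring(pop$claims, thr)))
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("mixed-practice providers blend two specialty blocks", {
  cfg <- simulationConfig(
    n_providers = 300, n_drugs = 40, n_classes = 8,
    specialties = specialtySpecs(40, 2, block_share = 1 - 1e-9),
    regions = regionSpecs(1), censor_threshold = 0, mixed_fraction = 0.5,
    seed = 31)
  pop <- generatePopulation(cfg)
  prof <- profileValues(buildProfiles(pop$claims, "drugs"))
  block1 <- rowSums(prof[, 1:20])
  mixed <- pop$truth$mixed[rownames(prof)]
  # pure providers sit near 0 or 1 on block 1; mixed providers in between
  expect_lt(median(abs(block1[mixed] - 0.5)), 0.2)
  expect_gt(mean(abs(block1[mixed] - 0.5) < 0.45), 0.9)
  expect_gt(mean(pmin(block1[!mixed], 1 - block1[!mixed]) < 0.05), 0.9)
})
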