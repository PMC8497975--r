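test_that("generated taxonomies are complete, nested and seed-deterministic", {
  tax <- generateTaxonomy(c(2, 3, 5, 8, 20), seed = 1)
  expect_identical(dim(tax), c(20L, 5L))
  expect_false(anyNA(tax))
  expect_identical(length(unique(tax$phylum)), 2L)
  expect_identical(length(unique(tax$genus)), 20L)
  # nesting: every child maps to exactly one parent
  for (k in 2:5) {
    pairs <- unique(tax[, c(k - 1, k)])
    expect_identical(nrow(pairs), length(unique(tax[[k]])))
  }
  expect_identical(generateTaxonomy(c(2, 3, 5, 8, 20), seed = 1), tax)
  expect_false(identical(generateTaxonomy(c(2, 3, 5, 8, 20), seed = 2), tax))
  expect_error(generateTaxonomy(c(5, 3, 5, 8, 20)), "nesting")
})

test_that("cohorts have the requested shape with multinomial column totals", {
  spec <- cohortSpec(nSubjects = 50, sites = dtSites(),
                     taxonomyCounts = c(4, 8, 15, 30, 80), poolSize = 40,
                     readDepth = 1500)
  at <- generateCohort(spec, seed = 6)
  expect_identical(ncol(at), 500L)
  expect_true(all(colSums(assay(at, "counts")) == 1500))
  expect_identical(sort(unique(sampleSites(at))), sort(dtSites()))
  expect_identical(length(unique(sampleSubjects(at))), 50L)
  expect_true(validObject(at))
})

test_that("cohorts are seed-deterministic and round-trip through the TSV io", {
  spec <- cohortSpec(nSubjects = 6, sites = c("A", "B"),
                     taxonomyCounts = c(3, 4, 6, 10, 30), poolSize = 20,
                     readDepth = 800)
  a <- generateCohort(spec, seed = 123)
  b <- generateCohort(spec, seed = 123)
  expect_identical(assay(a, "counts"), assay(b, "counts"))
  expect_false(identical(assay(generateCohort(spec, seed = 124), "counts"),
                         assay(a, "counts")))
  tsv <- withr::local_tempfile(); md <- withr::local_tempfile()
  writeAbundanceTable(a, tsv, metadataPath = md)
  back <- readAbundanceTable(tsv, md)
  expect_equal(assay(back, "counts"), assay(a, "counts"))
})

test_that("near-total occupancy removes richness accrual (z ~ 0)", {
  at <- smallCohort(seed = 55, nSubjects = 15, sites = "S", poolSize = 25,
                    occupancyBeta = c(200, 1), lognormalSigma = 0.5)
  ps <- interIndividualProfiles(at, "S", qGrid = 0, nResamples = 10, seed = 1)
  lg <- resampleLog(ps)
  expect_true(all(abs(lg$z) < 0.02))
})

test_that("pooled richness matches the closed-form occupancy expectation", {
  # E[S(n)] = sum_t (1 - (1 - pi_t)^n), averaged over pi ~ Beta(a, b):
  # P * (1 - B(a, b + n)/B(a, b)).
  a <- 1; b <- 3; P <- 40; n <- 6
  expected <- P * (1 - exp(lbeta(a, b + n) - lbeta(a, b)))
  spec <- cohortSpec(nSubjects = n, sites = "S",
                     taxonomyCounts = c(3, 5, 8, 15, 60), poolSize = P,
                     occupancyBeta = c(a, b), lognormalSigma = 0,
                     readDepth = 20000)
  rich <- vapply(1:200, function(i) {
    at <- generateCohort(spec, seed = 5000 + i)
    sum(rowSums(assay(at, "counts")) > 0)
  }, numeric(1))
  se <- sd(rich) / sqrt(length(rich))
  expect_lt(abs(mean(rich) - expected), 3 * se)
})

test_that("occupancy calibration hits the target slope via the closed form", {
  ab <- calibrateOccupancy(0.3, 1:100, 300)
  expect_gte(attr(ab, "slope"), 0.28)
  expect_lte(attr(ab, "slope"), 0.32)
  # monotonicity: smaller mean occupancy (larger b) -> steeper accrual
  slopes <- vapply(c(0.5, 2, 8, 32, 128), function(b) {
    ES <- 300 * (1 - exp(lbeta(1, b + 1:100) - lbeta(1, b)))
    unname(coef(lm(log(ES) ~ log(1:100)))[2])
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
  # limit behaviour: shrinking targets push the mean occupancy towards 1
  meanOcc <- vapply(c(0.3, 0.1, 0.02), function(z) {
    ab <- calibrateOccupancy(z, 1:50, 300)
    unname(ab["a"] / sum(ab))
  }, numeric(1))
  expect_true(all(diff(meanOcc) > 0))
  expect_gt(meanOcc[3], 0.8)
  expect_error(calibrateOccupancy(1.2, 1:50, 300), "targetZ")
})
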