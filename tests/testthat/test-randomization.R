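test_that("a group compared with its own copy is never significant", {
  at <- smallCohort(seed = 17, nSubjects = 12, sites = "S", poolSize = 40)
  ids <- sampleIDs(at)
  # duplicate the 6 group-A samples as a disjoint pseudo-group
  m <- assay(at, "counts")
  M <- cbind(m[, 1:6], m[, 1:6])
  colnames(M) <- c(paste0("a", 1:6), paste0("b", 1:6))
  meta <- data.frame(sample_id = colnames(M), subject_id = colnames(M),
                     site = rep(c("GA", "GB"), each = 6))
  att <- AbundanceTable(M, meta)
  r <- randomizationTest(att, paste0("a", 1:6), paste0("b", 1:6),
                         statistic = "z", q = 0, nPerm = 99, innerReps = 4,
                         seed = 1)
  expect_identical(r@significant, 0L)
  expect_gt(r@pValue, 0.5)
})

test_that("p-values are add-one corrected, seeded and symmetric in the groups", {
  at <- smallCohort(seed = 23, nSubjects = 16, sites = "S", poolSize = 40)
  ids <- sampleIDs(at)
  g1 <- ids[1:8]; g2 <- ids[9:16]
  r1 <- randomizationTest(at, g1, g2, "z", q = 0, nPerm = 49, innerReps = 3,
                          seed = 5)
  r2 <- randomizationTest(at, g2, g1, "z", q = 0, nPerm = 49, innerReps = 3,
                          seed = 5)
  expect_gt(r1@pValue, 0)                      # never exactly zero
  expect_lte(r1@pValue, 1)
  expect_equal(r1@observedDiff, r2@observedDiff, tolerance = 1e-9)
  r1b <- randomizationTest(at, g1, g2, "z", q = 0, nPerm = 49, innerReps = 3,
                           seed = 5)
  expect_identical(r1@pValue, r1b@pValue)
  expect_identical(r1@nullDiffs, r1b@nullDiffs)
  expect_error(randomizationTest(at, g1[1:3], g2, "z"), ">= 4 samples")
  expect_error(randomizationTest(at, g1, c(g1[1], g2[-1]), "z"), "disjoint")
})

test_that("tests with mostly-degenerate permutations are inconclusive", {
  # identical communities: z statistic undefined in every resample
  m <- matrix(rep(c(5, 3, 2), 10), nrow = 3,
              dimnames = list(paste0("G", 1:3), paste0("s", 1:10)))
  meta <- data.frame(sample_id = paste0("s", 1:10),
                     subject_id = paste0("u", 1:10),
                     site = rep(c("GA", "GB"), each = 5))
  at <- AbundanceTable(m, meta)
  r <- randomizationTest(at, paste0("s", 1:5), paste0("s", 6:10), "z",
                         q = 0, nPerm = 20, innerReps = 3, seed = 2)
  expect_true(r@inconclusive)
  expect_true(is.na(r@significant))
  expect_true(is.na(r@pValue))
})

test_that("the pairwise matrix tests every unordered pair once per order", {
  at <- smallCohort(seed = 31, nSubjects = 6, sites = dtSites(),
                    poolSize = 25, poolOverlap = 0.6,
                    taxonomyCounts = c(3, 5, 8, 15, 50), readDepth = 1000)
  sm <- pairwiseMatrix(at, statistic = "z", qGrid = 0, nPerm = 9,
                       innerReps = 2, seed = 3)
  codes <- significanceCodes(sm)
  expect_identical(dim(codes), c(10L, 10L))
  expect_true(all(is.na(diag(codes))))
  expect_identical(sum(!is.na(codes)), 90L)    # 45 pairs, mirrored
  expect_identical(codes, t(codes))
  expect_true(all(codes[!is.na(codes)] %in% c("0", "1", "x")))
  # percentages recomputable from the 0/1 calls
  pct <- significancePercent(sm)
  for (s in sm@sites) {
    calls <- sm@significant[s, setdiff(sm@sites, s), 1]
    expect_equal(unname(pct["q0", s]), 100 * mean(calls, na.rm = TRUE))
  }
})

test_that("multi-order codes join the q = 0 digit to the rest with a comma", {
  at <- smallCohort(seed = 37, nSubjects = 5, sites = c("A", "B", "C"),
                    poolSize = 20, taxonomyCounts = c(3, 4, 6, 10, 40),
                    readDepth = 800)
  sm <- pairwiseMatrix(at, statistic = "z", qGrid = c(0, 1, 2, 3), nPerm = 9,
                       innerReps = 2, seed = 4)
  codes <- significanceCodes(sm)
  off <- codes[!is.na(codes)]
  expect_true(all(grepl("^[01x],[01x]{3}$", off)))
})
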