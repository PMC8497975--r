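test_that("pooling is the element-wise sum and is permutation-invariant", {
  at <- toyTable()
  expect_equal(poolSamples(at, "s2"), assay(at, "counts")[, "s2"])
  expect_equal(poolSamples(at, c("s1", "s4")),
               assay(at, "counts")[, "s1"] + assay(at, "counts")[, "s4"])
  expect_equal(poolSamples(at, c("s3", "s1", "s5")),
               poolSamples(at, c("s5", "s3", "s1")))
  expect_error(poolSamples(at, "nope"), "unknown sample")
  expect_error(poolSamples(at, character(0)), "empty")
})

test_that("pooling disjoint-support samples unions their supports", {
  m <- matrix(0, 12, 2, dimnames = list(paste0("t", 1:12), c("a", "b")))
  m[1:5, 1] <- 1
  m[6:12, 2] <- 2
  at <- AbundanceTable(m, data.frame(sample_id = c("a", "b"),
                                     subject_id = c("u1", "u2"),
                                     site = "S"))
  expect_equal(sum(poolSamples(at, c("a", "b")) > 0), 12)
})

test_that("accrual curves behave on identical, disjoint and nested samples", {
  # identical samples: constant richness curve
  m <- matrix(rep(c(2, 3, 5), 4), nrow = 3,
              dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     subject_id = paste0("u", 1:4), site = "S")
  cv <- accrualCurve(AbundanceTable(m, meta), paste0("s", 1:4), q = 0)
  expect_equal(cv@diversities, rep(3, 4))

  # pairwise-disjoint samples of richness r: curve r, 2r, ..., nr
  r <- 3; n <- 4
  dm <- matrix(0, r * n, n, dimnames = list(paste0("t", seq_len(r * n)),
                                            paste0("s", seq_len(n))))
  for (j in seq_len(n)) dm[(j - 1) * r + seq_len(r), j] <- 1
  dat <- AbundanceTable(dm, data.frame(sample_id = paste0("s", 1:n),
                                       subject_id = paste0("u", 1:n),
                                       site = "S"))
  cv <- accrualCurve(dat, paste0("s", 1:n), q = 0)
  expect_equal(cv@diversities, r * seq_len(n))

  # nested supports accumulated largest-first: flat after A = 1
  nm <- matrix(0, 6, 3, dimnames = list(paste0("t", 1:6), paste0("s", 1:3)))
  nm[1:6, 1] <- 1; nm[1:4, 2] <- 1; nm[1:2, 3] <- 1
  nat <- AbundanceTable(nm, data.frame(sample_id = paste0("s", 1:3),
                                       subject_id = paste0("u", 1:3),
                                       site = "S"))
  cv <- accrualCurve(nat, c("s1", "s2", "s3"), q = 0)
  # brute-force union of supports
  supports <- lapply(1:3, function(k) which(rowSums(nm[, 1:k, drop = FALSE]) > 0))
  expect_equal(cv@diversities, lengths(supports))
  expect_equal(cv@diversities, c(6, 6, 6))
})

test_that("fitPL recovers an exact power law and flags constant curves", {
  f <- fitPL(modelCurve(10, c0 = 3, z = 0.5))
  expect_equal(f@z, 0.5, tolerance = 1e-10)
  expect_equal(f@c, 3, tolerance = 1e-10)
  expect_equal(f@R, 1, tolerance = 1e-10)
  expect_true(f@success)

  const <- new("AccrualCurve", areas = 1:8, diversities = rep(11, 8), q = 0)
  fc <- fitPL(const)
  expect_false(fc@success)
  expect_identical(fc@z, 0)
  expect_true(is.na(fc@R) && is.na(fc@pValue))

  expect_error(fitPL(new("AccrualCurve", areas = 1:2,
                         diversities = c(1, 2), q = 0)), "at least 3")
})

test_that("fitPL matches the normal-equations oracle and lm on noisy curves", {
  withr::with_seed(42, {
    for (i in 1:10) {
      A <- 1:20
      D <- 2.5 * A^0.4 * exp(rnorm(20, 0, 0.1))  # lognormal noise
      cv <- new("AccrualCurve", areas = A, diversities = D, q = 0)
      f <- fitPL(cv)
      # independent closed-form normal equations
      X <- cbind(1, log(A)); y <- log(D)
      beta <- solve(t(X) %*% X, t(X) %*% y)
      expect_equal(f@z, beta[2], tolerance = 1e-10)
      expect_equal(f@lnC, beta[1], tolerance = 1e-10)
      # and the standard regression machinery
      lmfit <- lm(y ~ log(A))
      expect_equal(f@z, unname(coef(lmfit)[2]), tolerance = 1e-10)
      sm <- summary(lmfit)
      expect_equal(f@pValue,
                   unname(pf(sm$fstatistic[1], 1, 18, lower.tail = FALSE)),
                   tolerance = 1e-8)
      expect_equal(f@R, abs(cor(y, fitted(lmfit))), tolerance = 1e-10)
    }
  })
})

test_that("fitPLEC recovers an exact cutoff model and reports d >= 0 fits", {
  f <- fitPLEC(modelCurve(30, c0 = 2, z = 0.4, d = -0.03))
  expect_equal(f@z, 0.4, tolerance = 1e-8)
  expect_equal(f@c, 2, tolerance = 1e-8)
  expect_equal(f@d, -0.03, tolerance = 1e-8)
  expect_true(f@success)
  expect_equal(f@Amax, 0.4 / 0.03, tolerance = 1e-8)

  # growing cutoff term: no finite maximum, fit still reported
  g <- fitPLEC(modelCurve(30, c0 = 2, z = 0.4, d = +0.02))
  expect_equal(g@d, 0.02, tolerance = 1e-8)
  expect_true(is.na(g@Dmax) && is.na(g@Amax))
  expect_false(g@success)

  expect_error(fitPLEC(new("AccrualCurve", areas = 1:3,
                           diversities = c(1, 2, 3), q = 0)), "at least 4")
})

test_that("fitPLEC matches a two-regressor normal-equations oracle", {
  withr::with_seed(99, {
    for (i in 1:10) {
      A <- 1:25
      D <- 1.7 * A^0.5 * exp(-0.04 * A) * exp(rnorm(25, 0, 0.05))
      cv <- new("AccrualCurve", areas = A, diversities = D, q = 1)
      f <- fitPLEC(cv)
      X <- cbind(1, log(A), A); y <- log(D)
      beta <- solve(t(X) %*% X, t(X) %*% y)
      expect_equal(f@lnC, beta[1], tolerance = 1e-10)
      expect_equal(f@z, beta[2], tolerance = 1e-10)
      expect_equal(f@d, beta[3], tolerance = 1e-10)
      sm <- summary(lm(y ~ log(A) + A))
      expect_equal(f@R, sqrt(sm$r.squared), tolerance = 1e-10)
      expect_equal(f@pValue,
                   unname(pf(sm$fstatistic[1], 2, 22, lower.tail = FALSE)),
                   tolerance = 1e-8)
    }
  })
})

test_that("pairwise diversity overlap has its analytic endpoints and monotonicity", {
  expect_identical(pdoFromZ(1), 0)
  expect_identical(pdoFromZ(0), 1)
  expect_equal(pdoFromZ(0.294), 2 - exp(0.294 * log(2)), tolerance = 1e-12)
  z <- seq(0, 1, by = 0.01)
  g <- pdoFromZ(z)
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(diff(g) < 0))
})

test_that("the PLEC maximum matches the model evaluated at Amax", {
  plec <- function(A, c0, z, d) c0 * A^z * exp(d * A)
  f <- fitPLEC(modelCurve(30, c0 = 1, z = 0.5, d = -0.05))
  m <- madFromPLEC(f)
  expect_equal(unname(m["Amax"]), 10, tolerance = 1e-8)
  expect_equal(unname(m["Dmax"]), 10^0.5 * exp(-0.5), tolerance = 1e-8)
  expect_equal(unname(m["Dmax"]), plec(unname(m["Amax"]), f@c, f@z, f@d),
               tolerance = 1e-10)

  # doubling c doubles Dmax, Amax unchanged
  f2 <- fitPLEC(modelCurve(30, c0 = 2, z = 0.5, d = -0.05))
  m2 <- madFromPLEC(f2)
  expect_equal(unname(m2["Amax"]), unname(m["Amax"]), tolerance = 1e-8)
  expect_equal(unname(m2["Dmax"]), 2 * unname(m["Dmax"]), tolerance = 1e-8)

  expect_error(madFromPLEC(fitPLEC(modelCurve(30, 2, 0.4, +0.01))),
               "undefined maximum")
})

test_that("Dmax is the analytic maximum of the PLEC curve on a grid", {
  plec <- function(A, c0, z, d) c0 * A^z * exp(d * A)
  for (c0 in c(0.5, 3)) for (z in c(0.2, 0.8)) for (d in c(-0.01, -0.2)) {
    Amax <- -z / d
    Dmax <- c0 * Amax^z * exp(-z)
    grid <- seq(max(Amax / 20, 1e-3), Amax * 5, length.out = 2000)
    expect_true(all(plec(grid, c0, z, d) <= Dmax + 1e-10 * Dmax))
    expect_equal(plec(Amax, c0, z, d), Dmax, tolerance = 1e-12)
  }
})

test_that("RIP is the percent ratio of individual to population diversity", {
  expect_equal(rip(5, 5), 100)
  expect_equal(rip(2, 8), 25)
  expect_error(rip(0, 5), "positive")
  expect_error(rip(2, -1), "positive")
})

test_that("RIP on a synthetic cohort tracks the simulated richness ratio", {
  at <- smallCohort(seed = 314, nSubjects = 40, sites = "S", poolSize = 120,
                    occupancyBeta = c(1, 5), lognormalSigma = 1,
                    taxonomyCounts = c(4, 8, 15, 40, 200))
  ps <- interIndividualProfiles(at, "S", qGrid = 0, nResamples = 20, seed = 7)
  st <- profileStats(ps)
  meanRichness <- mean(colSums(assay(at, "counts") > 0))
  direct <- 100 * meanRichness / st$mean_Dmax
  # same order of magnitude only: on a saturating accrual curve the PL
  # intercept c systematically exceeds the first-sample diversity
  expect_lt(abs(log(st$mean_RIP / direct)), log(2))
  expect_gt(st$mean_c, meanRichness)
})
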