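#' PermutationTestResult: randomization test for a DAR parameter difference
#'
#' Result of a two-group permutation (randomization) test on a
#' resampling-averaged DAR parameter (`z` from the PL fit or `Dmax` from the
#' PLEC fit) at one diversity order. The observed statistic of a group is the
#' mean fitted parameter over `innerReps` random accumulation orders
#' (successful fits only); the null distribution pools the two groups'
#' samples and re-splits them at random into pseudo-groups of the original
#' sizes. The p-value uses the add-one correction
#' `p = (1 + #(null >= observed)) / (n_valid + 1)`, so it is never zero, and
#' the test is two-sided through the absolute difference of group means.
#' Permutations whose statistic is degenerate (no successful fit in a
#' pseudo-group) are dropped; if more than half are degenerate the test is
#' reported inconclusive (`significant = NA`) rather than as a 0/1 call.
#'
#' @slot statisticName `"z"` or `"Dmax"`.
#' @slot q diversity order tested.
#' @slot observedDiff absolute difference of the two group statistics.
#' @slot nullDiffs null distribution (may contain `NA` for degenerate
#'   permutations).
#' @slot pValue Monte-Carlo p-value in `(0, 1]` (`NA` if inconclusive).
#' @slot significant integer 0/1 at `alpha`, `NA` if inconclusive.
#' @slot alpha significance level.
#' @slot nPerm number of permutations requested.
#' @slot inconclusive logical flag.
#' @slot groupSizes sizes of the two groups.
#' @export
setClass("PermutationTestResult",
  representation(statisticName = "character", q = "numeric",
                 observedDiff = "numeric", nullDiffs = "numeric",
                 pValue = "numeric", significant = "integer",
                 alpha = "numeric", nPerm = "integer",
                 inconclusive = "logical", groupSizes = "integer"))

setValidity("PermutationTestResult", function(object) {
  if (!object@inconclusive &&
      (!is.finite(object@pValue) || object@pValue <= 0 || object@pValue > 1))
    return("pValue must lie in (0, 1] for a conclusive test")
  TRUE
})

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf("Randomization test: %s at q = %g (groups %d vs %d, %d perms)\n",
              object@statisticName, object@q, object@groupSizes[1],
              object@groupSizes[2], object@nPerm))
  if (object@inconclusive) cat("  inconclusive (degenerate fits in majority of permutations)\n")
  else cat(sprintf("  observed |diff| = %.4g, p = %.4g, significant = %d\n",
                   object@observedDiff, object@pValue, object@significant))
})

## Mean fitted statistic of one sample group over `innerReps` random
## accumulation orders; NA when no fit succeeds.
.groupStatistic <- function(m, idx, statistic, q, innerReps) {
  vals <- numeric(0)
  la <- log(seq_along(idx))
  a <- seq_along(idx)
  for (i in seq_len(innerReps)) {
    cum <- .cumulativePool(m, sample(idx))
    y <- log(.hillRows(cum, q))
    if (statistic == "z") {
      f <- .plCore(la, y)
      if (f$success) vals <- c(vals, f$z)
    } else {
      f <- .plecCore(la, a, y)
      if (f$success)
        vals <- c(vals, exp(f$lnC) * (-f$z / f$d)^f$z * exp(-f$z))
    }
  }
  if (length(vals)) mean(vals) else NA_real_
}

#' Randomization test for a DAR parameter difference between two groups
#'
#' @param x an [AbundanceTable-class].
#' @param samplesA,samplesB disjoint sample-id sets (>= 4 samples each).
#' @param statistic `"z"` (PL scaling parameter) or `"Dmax"` (PLEC maximal
#'   accrual diversity).
#' @param q diversity order.
#' @param nPerm number of permutations (study design: 1000).
#' @param innerReps random accumulation orders per group statistic.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return a [PermutationTestResult][PermutationTestResult-class].
#' @seealso [pairwiseMatrix()] for all site pairs.
#' @export
randomizationTest <- function(x, samplesA, samplesB,
                              statistic = c("z", "Dmax"), q = 0,
                              nPerm = 1000, innerReps = 10, alpha = 0.05,
                              seed = NULL) {
  statistic <- match.arg(statistic)
  if (length(samplesA) < 4L || length(samplesB) < 4L)
    stop("both groups need >= 4 samples")
  if (length(intersect(samplesA, samplesB)))
    stop("groups must be disjoint")
  ## canonical group order: the test is symmetric in the two groups, so make
  ## the RNG stream identical whichever way the caller passes them
  if (paste(sort(samplesA), collapse = "\r") >
      paste(sort(samplesB), collapse = "\r")) {
    tmp <- samplesA; samplesA <- samplesB; samplesB <- tmp
  }
  m <- assay(x, "counts")
  idxA <- match(samplesA, sampleIDs(x))
  idxB <- match(samplesB, sampleIDs(x))
  if (anyNA(idxA) || anyNA(idxB)) stop("unknown sample id(s)")
  nA <- length(idxA)
  pool <- c(idxA, idxB)

  run <- function() {
    sA <- .groupStatistic(m, idxA, statistic, q, innerReps)
    sB <- .groupStatistic(m, idxB, statistic, q, innerReps)
    obs <- abs(sA - sB)
    nulls <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
      perm <- sample(pool)
      s1 <- .groupStatistic(m, perm[seq_len(nA)], statistic, q, innerReps)
      s2 <- .groupStatistic(m, perm[-seq_len(nA)], statistic, q, innerReps)
      nulls[b] <- abs(s1 - s2)
    }
    list(obs = obs, nulls = nulls)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  valid <- res$nulls[is.finite(res$nulls)]
  inconclusive <- !is.finite(res$obs) || length(valid) < nPerm / 2
  if (inconclusive) {
    p <- NA_real_; sig <- NA_integer_
  } else {
    p <- (1 + sum(valid >= res$obs)) / (length(valid) + 1)
    sig <- as.integer(p < alpha)
  }
  new("PermutationTestResult", statisticName = statistic, q = as.numeric(q),
      observedDiff = res$obs, nullDiffs = res$nulls, pValue = p,
      significant = sig, alpha = alpha, nPerm = as.integer(nPerm),
      inconclusive = inconclusive,
      groupSizes = c(length(idxA), length(idxB)))
}

#' SignificanceMatrix: coded pairwise site comparisons
#'
#' Site-by-site matrix of randomization-test outcomes. Each off-diagonal cell
#' carries a code string with one 0/1 digit per diversity order — the first
#' digit (q = 0) separated from the rest by a comma, e.g. `"0,000"` — where 1
#' marks a significant difference; inconclusive tests are coded `x`. The
#' per-site percentage of significant comparisons at each `q` is recomputable
#' from the codes.
#'
#' @slot sites site labels.
#' @slot statisticName tested statistic.
#' @slot qGrid diversity orders (one code digit each).
#' @slot codes character matrix of code strings (diagonal `NA`).
#' @slot significant 3-d array site x site x q of 0/1/NA.
#' @slot pValues 3-d array of Monte-Carlo p-values.
#' @slot percentSignificant matrix q x site of percentages.
#' @export
setClass("SignificanceMatrix",
  representation(sites = "character", statisticName = "character",
                 qGrid = "numeric", codes = "matrix",
                 significant = "array", pValues = "array",
                 percentSignificant = "matrix"))

setMethod("show", "SignificanceMatrix", function(object) {
  cat(sprintf("SignificanceMatrix: %s over %d sites, q = {%s}\n",
              object@statisticName, length(object@sites),
              paste(object@qGrid, collapse = ", ")))
  print(object@codes, quote = FALSE)
  cat("Percentage with significant differences (%):\n")
  print(round(object@percentSignificant, 1))
})

#' @describeIn SignificanceMatrix-class the code-string matrix.
#' @param x a `SignificanceMatrix`.
#' @export
significanceCodes <- function(x) x@codes

#' @describeIn SignificanceMatrix-class the q x site percentage matrix.
#' @export
significancePercent <- function(x) x@percentSignificant

.codeString <- function(digits) {
  ch <- ifelse(is.na(digits), "x", as.character(digits))
  if (length(ch) == 1L) return(ch)
  paste0(ch[1L], ",", paste(ch[-1L], collapse = ""))
}

#' Pairwise randomization tests among sites
#'
#' Runs [randomizationTest()] for every unordered pair of sites (C(n,2)
#' pairs) at every diversity order in `qGrid`, and assembles the coded
#' significance matrix with per-site percentages of significant comparisons.
#'
#' @param x an [AbundanceTable-class].
#' @param sites site labels (default: all observed, sorted).
#' @param statistic `"z"` or `"Dmax"`.
#' @param qGrid diversity orders (one code digit per order).
#' @param nPerm,innerReps,alpha passed to [randomizationTest()].
#' @param seed integer seed; per-pair seeds are derived deterministically.
#' @param dedupeSubjects keep one sample per subject per site.
#' @return a [SignificanceMatrix][SignificanceMatrix-class].
#' @export
pairwiseMatrix <- function(x, sites = NULL, statistic = c("z", "Dmax"),
                           qGrid = c(0, 1, 2, 3), nPerm = 1000,
                           innerReps = 10, alpha = 0.05, seed = NULL,
                           dedupeSubjects = TRUE) {
  statistic <- match.arg(statistic)
  if (is.null(sites)) sites <- sort(unique(sampleSites(x)))
  ns <- length(sites)
  if (ns < 2L) stop("need at least two sites")
  groups <- lapply(sites, siteSamples, x = x, dedupeSubjects = dedupeSubjects)
  names(groups) <- sites

  pairs <- utils::combn(ns, 2L)
  seeds <- .deriveSeeds(seed, ncol(pairs) * length(qGrid))
  sig <- array(NA_integer_, dim = c(ns, ns, length(qGrid)),
               dimnames = list(sites, sites, paste0("q", qGrid)))
  pv <- array(NA_real_, dim = dim(sig), dimnames = dimnames(sig))
  k <- 0L
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    for (qi in seq_along(qGrid)) {
      k <- k + 1L
      res <- randomizationTest(x, groups[[i1]], groups[[i2]],
                               statistic = statistic, q = qGrid[qi],
                               nPerm = nPerm, innerReps = innerReps,
                               alpha = alpha, seed = seeds[[k]])
      sig[i1, i2, qi] <- sig[i2, i1, qi] <- res@significant
      pv[i1, i2, qi] <- pv[i2, i1, qi] <- res@pValue
    }
  }

  codes <- matrix(NA_character_, ns, ns, dimnames = list(sites, sites))
  for (i1 in seq_len(ns)) for (i2 in seq_len(ns)) {
    if (i1 != i2) codes[i1, i2] <- .codeString(sig[i1, i2, ])
  }
  pct <- matrix(NA_real_, length(qGrid), ns,
                dimnames = list(paste0("q", qGrid), sites))
  for (i in seq_len(ns)) for (qi in seq_along(qGrid))
    pct[qi, i] <- 100 * mean(sig[i, -i, qi], na.rm = TRUE)

  new("SignificanceMatrix", sites = sites, statisticName = statistic,
      qGrid = as.numeric(qGrid), codes = codes, significant = sig,
      pValues = pv, percentSignificant = pct)
}
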