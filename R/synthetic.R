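#' CohortSpec: parameters of the synthetic multi-site cohort generator
#'
#' Describes a synthetic cohort with the statistical structure the DAR
#' analysis assumes: `nSubjects` individuals each sampled once at every site;
#' a nested 5-level taxonomy; per-site genus pools whose cross-site sharing
#' is set by `poolOverlap`; core-satellite occupancy (each pool taxon is
#' present in an individual with probability `pi ~ Beta(a, b)`); heavy-tailed
#' (lognormal) taxon abundances; and multinomial read counts at `readDepth`.
#'
#' Defaults mirror the shape of the digestive-tract study cohort: 242
#' subjects, the ten DT sites, a 14/28/55/110/400 phylum-to-genus taxonomy,
#' and a per-site pool of 300 genera (population-level genus richness of a
#' single site is of order 300 in that cohort).
#'
#' @slot nSubjects number of individuals.
#' @slot sites site labels.
#' @slot taxonomyCounts named integer vector of taxon counts per rank,
#'   non-decreasing from phylum to genus.
#' @slot poolSize genera in each site's pool.
#' @slot poolOverlap fraction of the pool shared by all sites, in `[0, 1]`.
#' @slot occupancyBeta `c(a, b)` shape parameters of the occupancy Beta law.
#' @slot lognormalSigma SD of per-taxon mean log-abundances.
#' @slot readDepth multinomial total per sample.
#' @export
setClass("CohortSpec",
  representation(nSubjects = "integer", sites = "character",
                 taxonomyCounts = "integer", poolSize = "integer",
                 poolOverlap = "numeric", occupancyBeta = "numeric",
                 lognormalSigma = "numeric", readDepth = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  tc <- object@taxonomyCounts
  if (length(tc) != 5L || any(tc < 1L))
    msg <- c(msg, "taxonomyCounts must be 5 positive counts (phylum..genus)")
  else if (any(diff(tc) < 0))
    msg <- c(msg, "taxonomyCounts must be non-decreasing down the ranks")
  if (object@poolSize > tc[5L])
    msg <- c(msg, "poolSize cannot exceed the number of genera")
  if (object@poolOverlap < 0 || object@poolOverlap > 1)
    msg <- c(msg, "poolOverlap must lie in [0, 1]")
  if (length(object@occupancyBeta) != 2L || any(object@occupancyBeta <= 0))
    msg <- c(msg, "occupancyBeta must be two positive shape parameters")
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be positive")
  if (object@readDepth < 1L) msg <- c(msg, "readDepth must be positive")
  if (object@lognormalSigma < 0) msg <- c(msg, "lognormalSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d subjects x %d sites; taxonomy %s; pool %d (overlap %.2f)\n",
    object@nSubjects, length(object@sites),
    paste(object@taxonomyCounts, collapse = "/"), object@poolSize,
    object@poolOverlap))
  cat(sprintf("  occupancy ~ Beta(%.3g, %.3g), lognormal sigma = %.3g, depth = %d\n",
              object@occupancyBeta[1], object@occupancyBeta[2],
              object@lognormalSigma, object@readDepth))
})

#' @rdname CohortSpec-class
#' @param nSubjects,sites,taxonomyCounts,poolSize,poolOverlap,occupancyBeta,lognormalSigma,readDepth
#'   see the class slots.
#' @return `cohortSpec()` returns a validated `CohortSpec`.
#' @examples
#' cohortSpec(nSubjects = 20, sites = c("A", "B"),
#'            taxonomyCounts = c(3, 4, 6, 10, 40), poolSize = 30)
#' @export
cohortSpec <- function(nSubjects = 242, sites = dtSites(),
                       taxonomyCounts = c(phylum = 14, class = 28,
                                          order = 55, family = 110,
                                          genus = 400),
                       poolSize = 300, poolOverlap = 0.5,
                       occupancyBeta = c(1, 10), lognormalSigma = 2,
                       readDepth = 10000) {
  tc <- as.integer(taxonomyCounts)
  names(tc) <- .TAXON_RANKS
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      sites = as.character(sites), taxonomyCounts = tc,
      poolSize = as.integer(poolSize), poolOverlap = as.numeric(poolOverlap),
      occupancyBeta = as.numeric(occupancyBeta),
      lognormalSigma = as.numeric(lognormalSigma),
      readDepth = as.integer(readDepth))
}

#' Generate a nested random taxonomy
#'
#' Randomly assigns genera to families, families to orders, orders to classes
#' and classes to phyla so that every parent receives at least one child and
#' every genus carries a complete 5-level lineage. Deterministic under `seed`.
#'
#' @param spec a [CohortSpec][CohortSpec-class], or a vector of 5 taxon counts
#'   (phylum, class, order, family, genus).
#' @param seed integer seed.
#' @return data.frame with columns `phylum..genus`, one row per genus,
#'   rownames the genus labels.
#' @examples
#' tax <- generateTaxonomy(c(2, 3, 5, 8, 20), seed = 1)
#' head(tax)
#' @export
generateTaxonomy <- function(spec, seed = NULL) {
  counts <- if (is(spec, "CohortSpec")) spec@taxonomyCounts
            else as.integer(spec)
  if (length(counts) != 5L || any(counts < 1L))
    stop("need 5 positive taxon counts (phylum..genus)")
  if (any(diff(counts) < 0))
    stop("impossible nesting: more parents than children at some rank")
  run <- function() {
    labels <- lapply(seq_along(.TAXON_RANKS), function(k)
      sprintf("%s%0*d", toupper(substr(.TAXON_RANKS[k], 1, 1)),
              nchar(counts[k]), seq_len(counts[k])))
    ## parent index per child at each rank below phylum: surjective + random
    parentOf <- lapply(2:5, function(k) {
      nP <- counts[k - 1L]; nC <- counts[k]
      sample(c(seq_len(nP),
               if (nC > nP) sample.int(nP, nC - nP, replace = TRUE)))
    })
    lin <- matrix(NA_character_, nrow = counts[5L], ncol = 5L,
                  dimnames = list(labels[[5L]], .TAXON_RANKS))
    lin[, "genus"] <- labels[[5L]]
    idx <- seq_len(counts[5L])
    for (k in 4:1) {
      idx <- parentOf[[k]][idx]          # parent at rank k of each genus
      lin[, k] <- labels[[k]][idx]
    }
    as.data.frame(lin, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a synthetic multi-site cohort
#'
#' Draws one sample per subject and site. Per site, a genus pool of
#' `poolSize` taxa is formed from a core shared by all sites
#' (`poolOverlap` fraction) plus site-specific taxa; each pool taxon gets an
#' occupancy probability `pi ~ Beta(a, b)` and a mean log-abundance
#' `mu ~ N(0, lognormalSigma^2)`. Each subject carries a pool taxon with
#' probability `pi`; carried taxa receive lognormal relative abundances
#' `exp(mu + e)`, `e ~ N(0, 1)`, and read counts are multinomial at
#' `readDepth`. The realized occupancies and site pools are stored in
#' `metadata(x)$generator` so closed-form expectations (e.g. expected pooled
#' richness `sum_t 1 - (1 - pi_t)^n`) can be checked against the output.
#'
#' @param spec a [CohortSpec][CohortSpec-class].
#' @param seed integer seed; the same seed reproduces the table bitwise.
#' @return an [AbundanceTable-class] with `nSubjects * length(sites)` samples.
#' @examples
#' at <- generateCohort(cohortSpec(nSubjects = 6, sites = c("A", "B"),
#'                                 taxonomyCounts = c(2, 3, 4, 6, 20),
#'                                 poolSize = 12, readDepth = 500), seed = 7)
#' at
#' @export
generateCohort <- function(spec, seed = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  run <- function() {
    tax <- generateTaxonomy(spec)
    genera <- rownames(tax)
    P <- spec@poolSize
    a <- spec@occupancyBeta[1L]; b <- spec@occupancyBeta[2L]
    nCore <- round(spec@poolOverlap * P)
    core <- sample(genera, nCore)
    rest <- setdiff(genera, core)

    sitePools <- list(); occ <- list(); logMean <- list()
    for (s in spec@sites) {
      extra <- if (P > nCore) sample(rest, P - nCore) else character(0)
      pool <- c(core, extra)
      sitePools[[s]] <- pool
      pi_t <- rbeta(P, a, b)
      occ[[s]] <- setNames(pi_t, pool)
      ## core-satellite coupling: widely occupant taxa are also the abundant
      ## ones. The Beta CDF transform makes mu a monotone function of pi with
      ## an exactly N(0, sigma^2) marginal.
      u <- pmin(pmax(stats::pbeta(pi_t, a, b), 1e-12), 1 - 1e-12)
      logMean[[s]] <- setNames(spec@lognormalSigma * stats::qnorm(u), pool)
    }

    taxa <- sort(unique(unlist(sitePools)))
    subjects <- sprintf("sub%0*d", nchar(spec@nSubjects),
                        seq_len(spec@nSubjects))
    nSamp <- spec@nSubjects * length(spec@sites)
    counts <- matrix(0, nrow = length(taxa), ncol = nSamp,
                     dimnames = list(taxa, NULL))
    sampleId <- character(nSamp); subjId <- character(nSamp)
    siteId <- character(nSamp)

    j <- 0L
    for (s in spec@sites) {
      pool <- sitePools[[s]]
      pi_t <- occ[[s]]; mu_t <- logMean[[s]]
      rowIx <- match(pool, taxa)
      for (u in subjects) {
        j <- j + 1L
        present <- runif(P) < pi_t
        if (!any(present)) present[which.max(pi_t)] <- TRUE
        w <- exp(mu_t[present] + rnorm(sum(present)))
        counts[rowIx[present], j] <-
          as.numeric(rmultinom(1L, spec@readDepth, w))
        sampleId[j] <- paste(u, s, sep = "_")
        subjId[j] <- u; siteId[j] <- s
      }
    }
    colnames(counts) <- sampleId
    keep <- rowSums(counts) > 0          # taxa never drawn stay out
    counts <- counts[keep, , drop = FALSE]

    at <- AbundanceTable(
      counts,
      data.frame(sample_id = sampleId, subject_id = subjId, site = siteId),
      lineages = tax[rownames(counts), , drop = FALSE])
    metadata(at)$generator <- list(spec = spec, sitePools = sitePools,
                                   occupancy = occ, logMean = logMean)
    at
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## Closed-form log-log slope of the expected richness-accrual curve
## E[S(n)] = P * (1 - B(a, b + n)/B(a, b)) over the integer range nRange.
.occupancySlope <- function(a, b, nRange, poolSize) {
  ES <- poolSize * (1 - exp(lbeta(a, b + nRange) - lbeta(a, b)))
  x <- log(nRange); y <- log(ES)
  dx <- x - mean(x)
  sum(dx * (y - mean(y))) / sum(dx * dx)
}

#' Calibrate occupancy shapes to a target richness-accrual slope
#'
#' Finds Beta shape parameters `(a, b)` for the per-taxon occupancy law such
#' that the log-log slope of the expected pooled-richness curve
#' `E[S(n)] = P * (1 - B(a, b + n)/B(a, b))` over `nRange` matches `targetZ`
#' to within `tol`. The slope is monotone increasing in `b` for fixed `a`
#' (rarer taxa accrue longer), so the search is a bisection on `log b` over a
#' small grid of `a` values; the closed form is used throughout, with no
#' simulation.
#'
#' @param targetZ target slope in `(0, 1)`.
#' @param nRange integer range of accumulated individuals the slope is
#'   measured over (match it to the cohort size you will generate).
#' @param poolSize number of taxa in the site pool.
#' @param aGrid candidate Beta `a` shapes.
#' @param tol acceptable slope deviation (default 0.02).
#' @return named vector `c(a, b)` with attribute `"slope"`, the achieved
#'   closed-form slope.
#' @examples
#' ab <- calibrateOccupancy(0.3, 1:100, 300)
#' ab
#' attr(ab, "slope")
#' @export
calibrateOccupancy <- function(targetZ, nRange = 1:100, poolSize = 300,
                               aGrid = c(1, 0.5, 2, 0.25, 4), tol = 0.02) {
  if (targetZ <= 0 || targetZ >= 1)
    stop("targetZ must lie in (0, 1)")
  nRange <- as.integer(nRange)
  achieved <- c(Inf, -Inf)
  for (a in aGrid) {
    lo <- -8; hi <- 20                       # bisect on log(b)
    sLo <- .occupancySlope(a, exp(lo), nRange, poolSize)
    sHi <- .occupancySlope(a, exp(hi), nRange, poolSize)
    achieved <- c(min(achieved[1], sLo), max(achieved[2], sHi))
    if (targetZ < sLo || targetZ > sHi) next
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (.occupancySlope(a, exp(mid), nRange, poolSize) < targetZ) lo <- mid
      else hi <- mid
    }
    b <- exp((lo + hi) / 2)
    s <- .occupancySlope(a, b, nRange, poolSize)
    if (abs(s - targetZ) <= tol)
      return(structure(c(a = a, b = b), slope = s))
  }
  stop(sprintf(
    "calibration infeasible: target %.3g outside achievable slope range [%.3g, %.3g]",
    targetZ, achieved[1], achieved[2]))
}
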