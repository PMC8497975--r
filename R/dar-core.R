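#' AccrualCurve: diversity of a growing pooled community
#'
#' Holds the diversity-accrual curve obtained by pooling samples in a given
#' accumulation order: areas `A = 1..n` (number of accumulated area units) and
#' the Hill-number diversity `^qD` of the pooled community at each `A`.
#'
#' @slot areas integer vector `1..n`.
#' @slot diversities numeric vector of pooled `^qD` values.
#' @slot q the diversity order.
#' @export
setClass("AccrualCurve",
  representation(areas = "integer", diversities = "numeric", q = "numeric"))

setValidity("AccrualCurve", function(object) {
  msg <- character()
  if (length(object@areas) != length(object@diversities))
    msg <- c(msg, "areas and diversities must have equal length")
  if (length(object@areas) &&
      !identical(object@areas, seq_along(object@areas)))
    msg <- c(msg, "areas must be the consecutive integers 1..n")
  if (length(object@q) != 1L || object@q < 0)
    msg <- c(msg, "q must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AccrualCurve", function(object) {
  cat(sprintf("AccrualCurve (q = %g): %d area units, D(1) = %.4g, D(%d) = %.4g\n",
              object@q, length(object@areas), object@diversities[1],
              length(object@areas),
              object@diversities[length(object@diversities)]))
})

#' Pool the abundances of a set of samples
#'
#' Element-wise sum of the selected samples' abundance vectors; the pooled
#' vector is normalized downstream by [hillNumber()], so counts and relative
#' abundances behave identically. Pooling is permutation-invariant.
#'
#' @param x an [AbundanceTable-class].
#' @param sampleIds non-empty vector of sample ids present in `x`.
#' @return named numeric vector of pooled abundances over the taxa of `x`.
#' @export
poolSamples <- function(x, sampleIds) {
  if (!length(sampleIds)) stop("empty sample subset")
  idx <- match(sampleIds, sampleIDs(x))
  if (anyNA(idx))
    stop("unknown sample id(s): ",
         paste(head(sampleIds[is.na(idx)], 5), collapse = ", "))
  m <- assay(x, "counts")[, idx, drop = FALSE]
  rowSums(m)
}

## n x taxa matrix of cumulative pooled abundances for an ordered sample set;
## row A holds the pool of the first A samples.
.cumulativePool <- function(m, idx) {
  sub <- t(m[, idx, drop = FALSE])       # n x taxa
  if (nrow(sub) == 1L) return(sub)
  apply(sub, 2L, cumsum)
}

#' Build a diversity-accrual curve
#'
#' Accumulates the samples of `order` one at a time, pooling abundances
#' ([poolSamples()]) and computing the Hill-number diversity of the pool at
#' each step.
#'
#' @param x an [AbundanceTable-class].
#' @param order ordered, non-empty vector of sample ids: the accumulation
#'   order of the area units.
#' @param q diversity order.
#' @return an [AccrualCurve-class].
#' @examples
#' at <- generateCohort(cohortSpec(nSubjects = 8, sites = "Stool",
#'                                 taxonomyCounts = c(2, 3, 4, 6, 20),
#'                                 poolSize = 15, readDepth = 500), seed = 1)
#' accrualCurve(at, sampleIDs(at), q = 0)
#' @export
accrualCurve <- function(x, order, q) {
  if (!length(order)) stop("empty accumulation order")
  idx <- match(order, sampleIDs(x))
  if (anyNA(idx))
    stop("unknown sample id(s): ",
         paste(head(order[is.na(idx)], 5), collapse = ", "))
  cum <- .cumulativePool(assay(x, "counts"), idx)
  new("AccrualCurve", areas = seq_along(idx),
      diversities = as.numeric(.hillRows(cum, q)), q = as.numeric(q))
}

# ---------------------------------------------------------------------------
# PL / PLEC model fits
# ---------------------------------------------------------------------------

#' Power-law and exponential-cutoff fits of a diversity-accrual curve
#'
#' `PLFit` holds the log-linear least-squares fit of the power-law (PL) model
#' `D = c A^z`, i.e. `ln D = ln c + z ln A`; `PLECFit` the power law with
#' exponential cutoff (PLEC) `D = c A^z exp(dA)`, i.e.
#' `ln D = ln c + z ln A + dA`. `R` is the correlation between observed and
#' fitted `ln D`, `pValue` the regression F-test. A fit is successful when the
#' regression is estimable (enough points, positive variance of `ln D`,
#' full-rank design) and `pValue < 0.05`; a PLEC fit additionally requires
#' `d < 0` and `z > 0` so that the curve has a finite maximum. For such fits
#' `Amax = -z/d` and `Dmax = c Amax^z exp(-z)` are the accrual effort and
#' diversity at the curve's maximum; otherwise they are `NA`.
#'
#' @slot z,c,lnC,d fitted model parameters (`c = exp(lnC)`).
#' @slot R goodness-of-fit correlation in `[0, 1]` (`NA` when undefined).
#' @slot pValue regression F-test p-value (`NA` when undefined).
#' @slot success logical fit-success flag.
#' @slot nPoints number of curve points used.
#' @slot q diversity order of the fitted curve.
#' @slot Amax,Dmax PLEC-derived maximum (see above), `NA` when absent.
#' @aliases PLFit-class PLECFit-class
#' @name PLFit
NULL

#' @rdname PLFit
#' @export
setClass("PLFit",
  representation(z = "numeric", c = "numeric", lnC = "numeric",
                 R = "numeric", pValue = "numeric", success = "logical",
                 nPoints = "integer", q = "numeric"))

#' @rdname PLFit
#' @export
setClass("PLECFit", contains = "PLFit",
  representation(d = "numeric", Amax = "numeric", Dmax = "numeric"))

setValidity("PLFit", function(object) {
  if (length(object@success) == 1L && isTRUE(object@success) &&
      (!is.finite(object@R) || !is.finite(object@pValue)))
    return("a successful fit must have finite R and pValue")
  TRUE
})

setValidity("PLECFit", function(object) {
  if (isTRUE(object@success)) {
    if (!(object@d < 0 && object@z > 0 && object@Amax > 0))
      return("a successful PLEC fit requires d < 0, z > 0, Amax > 0")
    plec <- object@c * object@Amax^object@z * exp(object@d * object@Amax)
    if (abs(plec - object@Dmax) > 1e-10 * abs(object@Dmax))
      return("Dmax must equal the PLEC model evaluated at Amax")
  }
  TRUE
})

setMethod("show", "PLFit", function(object) {
  cat(sprintf("PL fit (q = %g, n = %d): z = %.4g, c = %.4g, R = %.4g, p = %.3g%s\n",
              object@q, object@nPoints, object@z, object@c, object@R,
              object@pValue, if (object@success) "" else "  [failed]"))
})

setMethod("show", "PLECFit", function(object) {
  cat(sprintf(
    "PLEC fit (q = %g, n = %d): z = %.4g, c = %.4g, d = %.4g, R = %.4g, p = %.3g%s\n",
    object@q, object@nPoints, object@z, object@c, object@d, object@R,
    object@pValue, if (object@success) "" else "  [failed]"))
  if (is.finite(object@Dmax))
    cat(sprintf("  Amax = %.4g, Dmax = %.4g\n", object@Amax, object@Dmax))
})

## ln D effectively constant -> the log-log regression is a horizontal line and
## R / p-value are undefined (the degenerate-fit failure mode).
.DEGENERATE_TOL <- 1e-12

## Closed-form simple OLS of y on x with F-test; returns a bare list.
.plCore <- function(lx, y) {
  n <- length(y)
  if (n < 3L) stop("PL fit needs at least 3 curve points")
  if (max(y) - min(y) < .DEGENERATE_TOL)
    return(list(z = 0, lnC = mean(y), R = NA_real_, p = NA_real_,
                success = FALSE, n = n))
  mx <- mean(lx); my <- mean(y)
  dx <- lx - mx; dy <- y - my
  sxx <- sum(dx * dx); sxy <- sum(dx * dy); syy <- sum(dy * dy)
  z <- sxy / sxx
  lnC <- my - z * mx
  r2 <- (sxy * sxy) / (sxx * syy)
  r2 <- min(r2, 1)
  R <- sqrt(r2)
  p <- if (r2 >= 1) 0 else stats::pf((n - 2) * r2 / (1 - r2), 1, n - 2,
                                     lower.tail = FALSE)
  list(z = z, lnC = lnC, R = R, p = p, success = is.finite(p) && p < 0.05,
       n = n)
}

## Two-regressor OLS (ln A, A) via QR with overall F-test.
.plecCore <- function(lx, a, y) {
  n <- length(y)
  if (n < 4L) stop("PLEC fit needs at least 4 curve points")
  if (max(y) - min(y) < .DEGENERATE_TOL)
    return(list(z = 0, lnC = mean(y), d = 0, R = NA_real_, p = NA_real_,
                success = FALSE, n = n))
  X <- cbind(1, lx, a)
  qrX <- qr(X)
  if (qrX$rank < 3L)
    return(list(z = NA_real_, lnC = NA_real_, d = NA_real_, R = NA_real_,
                p = NA_real_, success = FALSE, n = n))
  beta <- qr.coef(qrX, y)
  fit <- drop(X %*% beta)
  my <- mean(y)
  syy <- sum((y - my)^2)
  rss <- sum((y - fit)^2)
  r2 <- max(0, min(1, 1 - rss / syy))
  R <- sqrt(r2)
  p <- if (r2 >= 1 || rss <= 1e-24 * syy) 0 else
    stats::pf((r2 / 2) / ((1 - r2) / (n - 3)), 2, n - 3, lower.tail = FALSE)
  list(z = unname(beta[2L]), lnC = unname(beta[1L]), d = unname(beta[3L]),
       R = R, p = p,
       success = is.finite(p) && p < 0.05 && beta[3L] < 0 && beta[2L] > 0,
       n = n)
}

.asPLFit <- function(f, q) {
  new("PLFit", z = f$z, c = exp(f$lnC), lnC = f$lnC, R = f$R, pValue = f$p,
      success = f$success, nPoints = as.integer(f$n), q = as.numeric(q))
}

.asPLECFit <- function(f, q) {
  defined <- is.finite(f$d) && is.finite(f$z) && f$d < 0 && f$z > 0
  Amax <- if (defined) -f$z / f$d else NA_real_
  Dmax <- if (defined) exp(f$lnC) * Amax^f$z * exp(-f$z) else NA_real_
  new("PLECFit", z = f$z, c = exp(f$lnC), lnC = f$lnC, d = f$d, R = f$R,
      pValue = f$p, success = f$success, nPoints = as.integer(f$n),
      q = as.numeric(q), Amax = Amax, Dmax = Dmax)
}

#' Fit the power-law (PL) accrual model
#'
#' Ordinary least squares of `ln D` on `ln A` (the log-linear form of
#' `D = c A^z`). A curve whose `ln D` has zero variance (no accrual at all,
#' e.g. identical communities at `q = 0`) yields `success = FALSE` with
#' `z = 0` and undefined `R`/`pValue` rather than an error — the degenerate
#' constant-curve failure mode counted by the pipeline.
#'
#' @param curve an [AccrualCurve-class] with at least 3 points, all
#'   diversities positive.
#' @return a [PLFit][PLFit-class].
#' @export
fitPL <- function(curve) {
  stopifnot(is(curve, "AccrualCurve"))
  D <- curve@diversities
  if (any(D <= 0)) stop("all diversities must be positive for a log-log fit")
  .asPLFit(.plCore(log(as.numeric(curve@areas)), log(D)), curve@q)
}

#' Fit the power law with exponential cutoff (PLEC) accrual model
#'
#' Ordinary least squares of `ln D` on `(ln A, A)` (the log-linear form of
#' `D = c A^z exp(dA)`). When the fitted `d` is negative and `z` positive the
#' curve attains a finite maximum `Dmax` at `Amax = -z/d`; otherwise the fit
#' is reported with `Amax`/`Dmax` absent. Degenerate and rank-deficient
#' designs return `success = FALSE`.
#'
#' @param curve an [AccrualCurve-class] with at least 4 points, all
#'   diversities positive.
#' @return a [PLECFit][PLECFit-class].
#' @export
fitPLEC <- function(curve) {
  stopifnot(is(curve, "AccrualCurve"))
  D <- curve@diversities
  if (any(D <= 0)) stop("all diversities must be positive for a log-log fit")
  a <- as.numeric(curve@areas)
  .asPLECFit(.plecCore(log(a), a, log(D)), curve@q)
}

#' Pairwise diversity overlap from the scaling parameter
#'
#' The pairwise diversity overlap (PDO) implied by the PL scaling parameter:
#' `g = 2 - 2^z`. `z = 1` gives `g = 0` (no overlap between communities);
#' `z = 0` gives `g = 1` (total overlap); `g` is strictly decreasing in `z`
#' and lies in `[0, 1]` for `z` in `[0, 1]`.
#'
#' @param z scaling parameter(s); vectorized.
#' @return the overlap `g = 2 - 2^z`.
#' @examples
#' pdoFromZ(c(0, 0.294, 1))
#' @export
pdoFromZ <- function(z) 2 - 2^z

#' Maximal accrual diversity of a PLEC fit
#'
#' The PLEC curve `D = c A^z exp(dA)` with `d < 0 < z` attains its maximum at
#' `Amax = -z/d`, where the maximal accrual diversity (MAD) is
#' `Dmax = c Amax^z exp(-z)` — the model's estimate of the potential
#' (population-level) diversity.
#'
#' @param fit a successful [PLECFit][PLFit-class] with `d < 0` and `z > 0`.
#' @return named numeric vector `c(Amax, Dmax)`.
#' @export
madFromPLEC <- function(fit) {
  stopifnot(is(fit, "PLECFit"))
  if (!isTRUE(fit@success) || !(fit@d < 0 && fit@z > 0))
    stop("undefined maximum: requires a successful PLEC fit with d < 0 and z > 0")
  c(Amax = fit@Amax, Dmax = fit@Dmax)
}

#' Ratio of individual to population diversity (RIP)
#'
#' The PL parameter `c` is the expected diversity of the first accumulated
#' area unit (one individual's sample); `Dmax` is the population-level
#' maximal accrual diversity. Their ratio, in percent, measures how much of
#' the population diversity an average individual hosts.
#'
#' @param c positive PL parameter at the diversity order of interest.
#' @param dMax positive maximal accrual diversity at the same order.
#' @return `100 * c / dMax` (percent).
#' @examples
#' rip(2, 8)    # 25: one individual holds a quarter of the population pool
#' @export
rip <- function(c, dMax) {
  if (any(c <= 0) || any(dMax <= 0))
    stop("rip() requires positive c and dMax")
  100 * c / dMax
}
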