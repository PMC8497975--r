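#' DARProfileSet: resampling-averaged DAR parameters across diversity orders
#'
#' The per-group analogue of one block of the study's summary tables: for each
#' diversity order `q`, the mean and standard error of the PL/PLEC parameters
#' (`z`, `c`, `d`), the derived overlap `g = 2 - 2^z`, the maximal accrual
#' diversity `Dmax`, the individual-to-population ratio `RIP`, the
#' goodness-of-fit `R` and `p`, and `N_success` — the number of resamples
#' (out of `n_resamples`) in which both the PL and the PLEC fit succeeded and
#' `Dmax` was defined. All means and SEs are over those successful resamples
#' only, and `g` and `RIP` are computed per resample and then averaged (not
#' evaluated at the mean parameters). The full per-resample log is retained
#' so every summary column can be recomputed from it.
#'
#' @slot grouping site label, or `"intra-DT"` for the across-site design.
#' @slot taxonLevel taxonomic level of the analysed table.
#' @slot design `"inter-individual"` or `"intra-DT"`.
#' @slot qGrid diversity orders analysed.
#' @slot nResamples number of resampled accumulation orders.
#' @slot stats data.frame, one row per `q` (see [profileStats()]).
#' @slot resampleLog data.frame, one row per resample x `q`.
#' @export
setClass("DARProfileSet",
  representation(grouping = "character", taxonLevel = "character",
                 design = "character", qGrid = "numeric",
                 nResamples = "integer", stats = "data.frame",
                 resampleLog = "data.frame"))

setValidity("DARProfileSet", function(object) {
  s <- object@stats
  if (nrow(s) && any(s$N_success < 0 | s$N_success > s$n_resamples))
    return("N_success must lie in [0, n_resamples]")
  TRUE
})

setMethod("show", "DARProfileSet", function(object) {
  cat(sprintf("DARProfileSet [%s] %s, level = %s, %d resamples\n",
              object@design, object@grouping, object@taxonLevel,
              object@nResamples))
  print(format(object@stats, digits = 4), row.names = FALSE)
})

#' @describeIn DARProfileSet-class per-q summary table (columns `q, mean_z,
#'   se_z, mean_c, mean_d, mean_g, mean_Dmax, mean_RIP, R, p_value,
#'   N_success, n_resamples`).
#' @param x a `DARProfileSet`.
#' @export
profileStats <- function(x) {
  stopifnot(is(x, "DARProfileSet"))
  x@stats
}

#' @describeIn DARProfileSet-class per-resample fit log (one row per
#'   resample x q, with both fits' parameters and success flags).
#' @export
resampleLog <- function(x) {
  stopifnot(is(x, "DARProfileSet"))
  x@resampleLog
}

## Fit PL and PLEC at every q for one accumulation order; returns log rows.
## `cum` is the n x taxa cumulative pool matrix.
.fitResample <- function(cum, qGrid, resample) {
  n <- nrow(cum)
  a <- seq_len(n)
  la <- log(a)
  out <- vector("list", length(qGrid))
  for (k in seq_along(qGrid)) {
    q <- qGrid[k]
    y <- log(.hillRows(cum, q))
    pl <- .plCore(la, y)
    pe <- .plecCore(la, a, y)
    dmaxDefined <- is.finite(pe$d) && is.finite(pe$z) && pe$d < 0 && pe$z > 0
    Dmax <- if (dmaxDefined) exp(pe$lnC) * (-pe$z / pe$d)^pe$z * exp(-pe$z)
            else NA_real_
    ok <- pl$success && pe$success            # pe$success already needs d<0, z>0
    out[[k]] <- data.frame(
      resample = resample, q = q,
      z = pl$z, c = exp(pl$lnC), g = pdoFromZ(pl$z),
      R = pl$R, p = pl$p,
      d = pe$d, Dmax = Dmax,
      RIP = if (ok && is.finite(Dmax)) 100 * exp(pl$lnC) / Dmax else NA_real_,
      pl_success = pl$success, plec_success = pe$success, success = ok)
  }
  do.call(rbind, out)
}

## Summarize a per-resample log into the per-q stats table.
.summarizeLog <- function(logdf, qGrid, nResamples) {
  rows <- lapply(qGrid, function(q) {
    sub <- logdf[logdf$q == q & logdf$success, , drop = FALSE]
    N <- nrow(sub)
    mn <- function(v) if (N) mean(v) else NA_real_
    se <- function(v) if (N > 1) stats::sd(v) / sqrt(N) else NA_real_
    data.frame(q = q,
               mean_z = mn(sub$z), se_z = se(sub$z),
               mean_c = mn(sub$c), mean_d = mn(sub$d),
               mean_g = mn(sub$g), mean_Dmax = mn(sub$Dmax),
               mean_RIP = mn(sub$RIP),
               R = mn(sub$R), p_value = mn(sub$p),
               N_success = N, n_resamples = nResamples)
  })
  do.call(rbind, rows)
}

.newProfileSet <- function(logdf, qGrid, nResamples, grouping, level, design) {
  new("DARProfileSet", grouping = grouping, taxonLevel = level,
      design = design, qGrid = as.numeric(qGrid),
      nResamples = as.integer(nResamples),
      stats = .summarizeLog(logdf, qGrid, nResamples),
      resampleLog = logdf)
}

.tableLevel <- function(x) {
  rk <- intersect(.TAXON_RANKS, colnames(rowData(x)))
  if (length(rk)) rk[length(rk)] else "as-provided"
}

#' Inter-individual DAR profiles for one body site
#'
#' The cross-individual design: the area unit is one individual's sample at
#' the site. For each of `nResamples` resampled runs a uniformly random
#' accumulation order over the site's samples is drawn, the diversity-accrual
#' curve is built at every `q`, and the PL and PLEC models are fitted; the
#' reported profile is the average over successful fits, which removes the
#' dependence of the parameter `c` on any particular accumulation order.
#'
#' @param x an [AbundanceTable-class].
#' @param site site label with at least 4 samples (after keeping one sample
#'   per subject; see `dedupeSubjects`).
#' @param qGrid diversity orders (default `c(0, 1, 2, 3)`).
#' @param nResamples number of random accumulation orders (study design: 100).
#' @param seed integer seed for reproducibility.
#' @param dedupeSubjects keep one sample per subject (first by id sort).
#' @return a [DARProfileSet][DARProfileSet-class].
#' @export
interIndividualProfiles <- function(x, site, qGrid = c(0, 1, 2, 3),
                                    nResamples = 100, seed = NULL,
                                    dedupeSubjects = TRUE) {
  ids <- siteSamples(x, site, dedupeSubjects = dedupeSubjects)
  if (length(ids) < 4L)
    stop("inter-individual design needs >= 4 samples at site '", site, "'")
  m <- assay(x, "counts")
  idx <- match(ids, sampleIDs(x))
  run <- function() {
    logs <- vector("list", nResamples)
    for (r in seq_len(nResamples)) {
      ord <- sample(idx)
      logs[[r]] <- .fitResample(.cumulativePool(m, ord), qGrid, r)
    }
    do.call(rbind, logs)
  }
  logdf <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  .newProfileSet(logdf, qGrid, nResamples, site, .tableLevel(x),
                 "inter-individual")
}

#' Intra-tract DAR profiles across body sites
#'
#' The across-site design: the area unit is one body site. Each replicate
#' draws one sample uniformly at random from every site and accumulates the
#' ten units in the fixed anatomical order `siteOrder` (oral cavity towards
#' the intestinal tract by default); PL and PLEC fits at every `q` are
#' averaged over replicates.
#'
#' @param x an [AbundanceTable-class] containing at least one sample per site
#'   in `siteOrder`.
#' @param siteOrder ordered site labels (default [dtSiteOrder()]).
#' @param qGrid diversity orders.
#' @param nResamples number of replicates (study design: 1000).
#' @param seed integer seed.
#' @return a [DARProfileSet][DARProfileSet-class] with
#'   `grouping = "intra-DT"`.
#' @export
intraIndividualProfiles <- function(x, siteOrder = dtSiteOrder(),
                                    qGrid = c(0, 1, 2, 3), nResamples = 1000,
                                    seed = NULL) {
  bySite <- lapply(siteOrder, function(s) which(sampleSites(x) == s))
  empty <- siteOrder[vapply(bySite, length, integer(1)) == 0L]
  if (length(empty))
    stop("no samples at site(s): ", paste(empty, collapse = ", "))
  m <- assay(x, "counts")
  run <- function() {
    logs <- vector("list", nResamples)
    for (r in seq_len(nResamples)) {
      pick <- vapply(bySite, function(ix)
        if (length(ix) == 1L) ix else sample(ix, 1L), integer(1))
      logs[[r]] <- .fitResample(.cumulativePool(m, pick), qGrid, r)
    }
    do.call(rbind, logs)
  }
  logdf <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  .newProfileSet(logdf, qGrid, nResamples, "intra-DT", .tableLevel(x),
                 "intra-DT")
}

#' Run both DAR designs at multiple taxonomic levels
#'
#' Collapses the table to each requested level ([collapseToLevel()]) and runs
#' the inter-individual design per site and/or the intra-tract design,
#' returning one [DARProfileSet][DARProfileSet-class] per group x level.
#'
#' @param x an [AbundanceTable-class] with lineages populated.
#' @param levels taxonomic levels to analyse (subset of phylum..genus). Use
#'   `"asis"` to analyse the table as provided, without collapsing.
#' @param designs subset of `c("inter", "intra")`.
#' @param sites sites for the inter-individual design (default: all observed).
#' @param siteOrder accumulation order for the intra-tract design.
#' @param qGrid diversity orders.
#' @param nResamplesInter,nResamplesIntra resample counts per design.
#' @param seed integer seed; per-task seeds are derived deterministically.
#' @param dedupeSubjects passed to [interIndividualProfiles()].
#' @return named list of `DARProfileSet` (names `<level>.<group>`).
#' @seealso [profileTable()] to flatten the result, [writeProfileTable()]
#' @export
runAllLevels <- function(x,
                         levels = c("phylum", "class", "order", "family",
                                    "genus"),
                         designs = c("inter", "intra"),
                         sites = NULL, siteOrder = dtSiteOrder(),
                         qGrid = c(0, 1, 2, 3),
                         nResamplesInter = 100, nResamplesIntra = 1000,
                         seed = NULL, dedupeSubjects = TRUE) {
  designs <- match.arg(designs, several.ok = TRUE)
  if (is.null(sites)) sites <- sort(unique(sampleSites(x)))
  nTasks <- length(levels) * (length(sites) * ("inter" %in% designs) +
                              ("intra" %in% designs))
  seeds <- .deriveSeeds(seed, nTasks)
  out <- list()
  k <- 0L
  for (lev in levels) {
    tab <- if (identical(lev, "asis")) x else collapseToLevel(x, lev)
    if ("inter" %in% designs) {
      for (s in sites) {
        k <- k + 1L
        out[[paste(lev, s, sep = ".")]] <-
          interIndividualProfiles(tab, s, qGrid = qGrid,
                                  nResamples = nResamplesInter,
                                  seed = seeds[[k]],
                                  dedupeSubjects = dedupeSubjects)
      }
    }
    if ("intra" %in% designs) {
      k <- k + 1L
      out[[paste(lev, "intra-DT", sep = ".")]] <-
        intraIndividualProfiles(tab, siteOrder = siteOrder, qGrid = qGrid,
                                nResamples = nResamplesIntra, seed = seeds[[k]])
    }
  }
  out
}

#' Flatten profile sets into one tidy table
#'
#' @param profiles a `DARProfileSet` or a list of them (as returned by
#'   [runAllLevels()]).
#' @return data.frame with one row per group x level x q.
#' @export
profileTable <- function(profiles) {
  if (is(profiles, "DARProfileSet")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    cbind(data.frame(design = p@design, grouping = p@grouping,
                     taxon_level = p@taxonLevel), p@stats)
  })) |> (\(d) { rownames(d) <- NULL; d })()
}

#' @rdname profileTable
#' @param path output TSV path.
#' @return `writeProfileTable` returns `path` invisibly.
#' @export
writeProfileTable <- function(profiles, path) {
  data.table::fwrite(profileTable(profiles), path, sep = "\t")
  invisible(path)
}

## Derive n deterministic sub-seeds (< 2^31) from one seed; NULL passes NULLs.
.deriveSeeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  as.list(withr::with_seed(seed, sample.int(.Machine$integer.max, n)))
}
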