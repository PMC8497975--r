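#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom stats var cor pf rbeta rnorm rmultinom runif sd setNames
#' @importFrom utils head
NULL

## canonical rank order, coarse -> fine
.TAXON_RANKS <- c("phylum", "class", "order", "family", "genus")

#' Digestive-tract site labels
#'
#' The ten digestive-tract (DT) body-site labels used throughout the package:
#' seven oral sites (buccal mucosa BM, keratinized gingiva KG, hard palate HP,
#' throat Th, palatine tonsils PT, tongue dorsum TD, saliva Sal), the supra-
#' and subgingival plaques (SupP, SubP), and stool.
#'
#' @return `dtSites()` returns the ten site labels; `dtSiteOrder()` returns
#'   them in the default anatomical accumulation order used by the intra-tract
#'   design, running from the oral cavity towards the intestinal tract.
#' @examples
#' dtSites()
#' dtSiteOrder()
#' @export
dtSites <- function() {
  c("BM", "KG", "HP", "Th", "PT", "TD", "Sal", "SupP", "SubP", "Stool")
}

#' @rdname dtSites
#' @export
dtSiteOrder <- function() {
  c("BM", "KG", "HP", "TD", "PT", "Th", "Sal", "SupP", "SubP", "Stool")
}

#' AbundanceTable: a taxon-abundance matrix with cohort metadata
#'
#' `AbundanceTable` extends [SummarizedExperiment::SummarizedExperiment] and is
#' the universal input of the package: a non-negative abundance matrix (read
#' counts or relative abundances) with taxa as rows and samples as columns,
#' per-sample `subject_id` and `site` in `colData`, and per-taxon lineage
#' labels (phylum, class, order, family, genus) in `rowData`.
#'
#' All diversity computations normalize abundances internally, so counts and
#' relative abundances are interchangeable.
#'
#' @slot .. inherited from `SummarizedExperiment`; the single assay is named
#'   `"counts"`.
#' @aliases AbundanceTable-class
#' @seealso [readAbundanceTable()], [collapseToLevel()], [generateCohort()]
#' @export
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (!is.numeric(m)) msg <- c(msg, "'counts' must be numeric")
    else {
      if (anyNA(m)) msg <- c(msg, "'counts' must not contain NA")
      else if (any(m < 0)) msg <- c(msg, "'counts' must be non-negative")
      else if (ncol(m) > 0 && any(colSums(m) <= 0))
        msg <- c(msg, "every sample must have a positive total abundance")
    }
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon ids (rownames) must be present and unique")
  cd <- colData(object)
  if (!all(c("subject_id", "site") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'subject_id' and 'site'")
  rd <- rowData(object)
  ranks <- intersect(.TAXON_RANKS, colnames(rd))
  if (length(ranks) && !identical(ranks, .TAXON_RANKS[seq_along(ranks)]))
    msg <- c(msg, "lineage columns must be a coarse-to-fine prefix of phylum..genus")
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param counts numeric matrix of non-negative abundances, taxa in rows and
#'   samples in columns, with unique dimnames. A samples-by-taxa matrix is
#'   accepted when `samplesAsRows = TRUE`.
#' @param sampleData data.frame with one row per sample and columns
#'   `sample_id` (or rownames), `subject_id` and `site`.
#' @param lineages per-taxon lineage labels: either a data.frame with columns
#'   among `phylum, class, order, family, genus` (rownames or a `taxon_id`
#'   column matching taxa), or a character vector of semicolon-separated
#'   lineage strings (rank prefixes such as `"p__"` are stripped). May be
#'   `NULL` when no taxonomic collapsing is needed.
#' @param samplesAsRows logical; set `TRUE` when `counts` has samples in rows.
#' @param dropEmptySamples logical; drop all-zero samples with a warning
#'   instead of failing validity.
#' @return a validated [AbundanceTable-class] object.
#' @examples
#' m <- matrix(rpois(12, 5) + 1, nrow = 4,
#'             dimnames = list(paste0("G", 1:4), paste0("s", 1:3)))
#' meta <- data.frame(sample_id = paste0("s", 1:3),
#'                    subject_id = paste0("sub", 1:3), site = "Stool")
#' at <- AbundanceTable(m, meta)
#' at
#' @export
AbundanceTable <- function(counts, sampleData, lineages = NULL,
                           samplesAsRows = FALSE, dropEmptySamples = TRUE) {
  counts <- as.matrix(counts)
  if (samplesAsRows) counts <- t(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have taxon rownames and sample colnames")

  sampleData <- as.data.frame(sampleData)
  if ("sample_id" %in% colnames(sampleData))
    rownames(sampleData) <- sampleData$sample_id
  missingMeta <- setdiff(colnames(counts), rownames(sampleData))
  if (length(missingMeta))
    stop("samples missing from metadata: ",
         paste(head(missingMeta, 5), collapse = ", "))
  sampleData <- sampleData[colnames(counts), , drop = FALSE]

  if (dropEmptySamples) {
    tot <- colSums(counts)
    if (any(tot <= 0)) {
      warning(sum(tot <= 0), " sample(s) with zero total abundance dropped: ",
              paste(head(colnames(counts)[tot <= 0], 5), collapse = ", "))
      counts <- counts[, tot > 0, drop = FALSE]
      sampleData <- sampleData[tot > 0, , drop = FALSE]
    }
  }

  rd <- .lineageDataFrame(lineages, rownames(counts))
  se <- SummarizedExperiment(
    assays = SimpleList(counts = counts),
    rowData = rd,
    colData = DataFrame(sampleData)
  )
  new("AbundanceTable", se)
}

## Normalize lineage input to a DataFrame aligned with taxon ids.
.lineageDataFrame <- function(lineages, taxa) {
  if (is.null(lineages)) return(DataFrame(row.names = taxa))
  if (is.character(lineages)) {
    if (length(lineages) != length(taxa))
      stop("lineage strings must match the number of taxa")
    lineages <- parseLineageStrings(lineages)
    rownames(lineages) <- taxa
  }
  lineages <- as.data.frame(lineages)
  if ("taxon_id" %in% colnames(lineages)) {
    rownames(lineages) <- lineages$taxon_id
    lineages$taxon_id <- NULL
  }
  keep <- intersect(.TAXON_RANKS, colnames(lineages))
  lineages <- lineages[, keep, drop = FALSE]
  miss <- setdiff(taxa, rownames(lineages))
  if (length(miss))
    stop("taxa missing from lineages: ", paste(head(miss, 5), collapse = ", "))
  DataFrame(lineages[taxa, , drop = FALSE])
}

#' Parse semicolon-separated lineage strings
#'
#' Splits lineage strings such as
#' `"p__Firmicutes;c__Bacilli;o__Lactobacillales;f__...;g__..."` into a
#' data.frame with columns `phylum..genus`, stripping single-letter rank
#' prefixes and trimming whitespace. Missing trailing ranks become `NA`.
#'
#' @param x character vector of lineage strings.
#' @return data.frame with columns `phylum, class, order, family, genus`.
#' @examples
#' parseLineageStrings("p__Firmicutes; c__Bacilli; o__Lactobacillales")
#' @export
parseLineageStrings <- function(x) {
  parts <- strsplit(as.character(x), ";", fixed = TRUE)
  out <- matrix(NA_character_, nrow = length(x), ncol = length(.TAXON_RANKS),
                dimnames = list(NULL, .TAXON_RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[a-zA-Z]__", "", p)
    p[p == ""] <- NA_character_
    n <- min(length(p), length(.TAXON_RANKS))
    out[i, seq_len(n)] <- p[seq_len(n)]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Accessors for AbundanceTable
#'
#' `sampleIDs` and `taxonIDs` return the sample and taxon identifiers;
#' `sampleSites` and `sampleSubjects` the per-sample site and subject labels;
#' `lineages` the per-taxon lineage table.
#'
#' @param x an [AbundanceTable-class].
#' @return character vectors, or a `DataFrame` for `lineages`.
#' @name AbundanceTable-accessors
NULL

#' @rdname AbundanceTable-accessors
#' @export
sampleIDs <- function(x) colnames(x)

#' @rdname AbundanceTable-accessors
#' @export
taxonIDs <- function(x) rownames(x)

#' @rdname AbundanceTable-accessors
#' @export
sampleSites <- function(x) as.character(colData(x)$site)

#' @rdname AbundanceTable-accessors
#' @export
sampleSubjects <- function(x) as.character(colData(x)$subject_id)

#' @rdname AbundanceTable-accessors
#' @export
lineages <- function(x) rowData(x)[, intersect(.TAXON_RANKS, colnames(rowData(x))),
                                   drop = FALSE]

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable:", nrow(object), "taxa x", ncol(object), "samples\n")
  st <- table(sampleSites(object))
  cat("  sites:", paste(sprintf("%s(%d)", names(st), st), collapse = " "), "\n")
  rk <- intersect(.TAXON_RANKS, colnames(rowData(object)))
  cat("  lineage ranks:",
      if (length(rk)) paste(rk, collapse = ", ") else "<none>", "\n")
})

#' Select the per-site analysis samples
#'
#' Returns the sample ids at a site, optionally keeping a single sample per
#' subject (the first by sample-id sort) so that each accumulated area unit is
#' one individual.
#'
#' @param x an [AbundanceTable-class].
#' @param site site label.
#' @param dedupeSubjects keep one sample per subject (default `TRUE`).
#' @return character vector of sample ids.
#' @export
siteSamples <- function(x, site, dedupeSubjects = TRUE) {
  ids <- sampleIDs(x)[sampleSites(x) == site]
  if (!length(ids)) stop("no samples at site '", site, "'")
  if (dedupeSubjects) {
    subj <- sampleSubjects(x)[match(ids, sampleIDs(x))]
    ids <- vapply(split(ids, subj), function(s) sort(s)[1], character(1))
    ids <- unname(sort(ids))
  }
  ids
}
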