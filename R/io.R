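#' Read an abundance table with sample metadata
#'
#' Reads a taxon-abundance table from TSV or BIOM together with a sample
#' metadata TSV (columns `sample_id`, `subject_id`, `site`) and returns a
#' validated [AbundanceTable-class]. All-zero samples are dropped with a
#' warning; samples absent from the metadata are an error.
#'
#' For TSV input the orientation (taxa in rows vs samples in rows) is
#' auto-detected by matching the table's row and column identifiers against
#' the metadata sample ids; tables matching in both orientations (or neither)
#' are rejected. A `taxonomy`/`lineage` column, when present, supplies
#' semicolon-separated lineage strings. BIOM input (JSON or HDF5) is read with
#' \pkg{biomformat}; observation metadata provides the lineages when present.
#'
#' @param path path to the abundance table.
#' @param metadataPath path to the sample-metadata TSV.
#' @param format `"tsv"` or `"biom"`.
#' @return an [AbundanceTable-class].
#' @seealso [writeAbundanceTable()]
#' @export
readAbundanceTable <- function(path, metadataPath, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("abundance table not found: ", path)
  if (!file.exists(metadataPath)) stop("metadata file not found: ", metadataPath)
  meta <- .readMetadata(metadataPath)
  parsed <- switch(format,
    tsv = .readTSVTable(path, meta$sample_id),
    biom = .readBIOMTable(path)
  )
  AbundanceTable(parsed$counts, meta, lineages = parsed$lineages)
}

.readMetadata <- function(path) {
  meta <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("sample_id", "subject_id", "site")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  meta
}

.readTSVTable <- function(path, sampleIds) {
  dt <- tryCatch(
    as.data.frame(data.table::fread(path, sep = "\t", header = TRUE)),
    error = function(e) stop("failed to parse TSV '", path, "': ",
                             conditionMessage(e))
  )
  if (ncol(dt) < 2) stop("abundance TSV needs an id column plus data columns")
  ids <- as.character(dt[[1L]])
  taxCol <- intersect(c("taxonomy", "lineage"), colnames(dt))[1]
  lineageStrings <- NULL
  if (!is.na(taxCol)) {
    lineageStrings <- as.character(dt[[taxCol]])
    dt[[taxCol]] <- NULL
  }
  valueCols <- colnames(dt)[-1L]

  rowHits <- mean(ids %in% sampleIds)
  colHits <- mean(valueCols %in% sampleIds)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in abundance TSV")
  rownames(m) <- ids

  if (colHits > 0.5 && rowHits <= 0.5) {
    lineages <- lineageStrings            # taxa in rows
  } else if (rowHits > 0.5 && colHits <= 0.5) {
    if (!is.null(lineageStrings))
      stop("taxonomy column is only valid with taxa in rows")
    m <- t(m)                             # samples in rows
    lineages <- NULL
  } else {
    stop("cannot determine table orientation: row and column ids ",
         "match the metadata sample ids ambiguously")
  }
  list(counts = m, lineages = lineages)
}

.readBIOMTable <- function(path) {
  b <- tryCatch(biomformat::read_biom(path),
                error = function(e) stop("failed to parse BIOM '", path, "': ",
                                         conditionMessage(e)))
  m <- as(biomformat::biom_data(b), "matrix")   # observations x samples
  lineages <- NULL
  om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  if (!is.null(om)) {
    if (is.data.frame(om) && ncol(om) >= 1) {
      strings <- apply(om, 1L, function(r) paste(r[!is.na(r)], collapse = ";"))
      lineages <- parseLineageStrings(strings)
      rownames(lineages) <- rownames(m)
    } else if (is.list(om)) {
      strings <- vapply(om, function(r) paste(unlist(r), collapse = ";"),
                        character(1))
      lineages <- parseLineageStrings(strings)
      rownames(lineages) <- rownames(m)
    }
  }
  list(counts = m, lineages = lineages)
}

#' Write an abundance table (and optionally its metadata) to TSV
#'
#' Writes taxa in rows with a leading `taxon_id` column and, when lineages are
#' present, a trailing semicolon-separated `taxonomy` column, so the file
#' round-trips through [readAbundanceTable()].
#'
#' @param x an [AbundanceTable-class].
#' @param path output TSV path.
#' @param metadataPath optional path for the sample-metadata TSV.
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(x, path, metadataPath = NULL) {
  m <- assay(x, "counts")
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
  lin <- lineages(x)
  if (ncol(lin)) {
    df$taxonomy <- apply(as.data.frame(lin), 1L, function(r)
      paste(ifelse(is.na(r), "", r), collapse = ";"))
  }
  data.table::fwrite(df, path, sep = "\t")
  if (!is.null(metadataPath)) {
    md <- data.frame(sample_id = sampleIDs(x),
                     subject_id = sampleSubjects(x),
                     site = sampleSites(x))
    data.table::fwrite(md, metadataPath, sep = "\t")
  }
  invisible(path)
}

#' Collapse taxa to a higher taxonomic level
#'
#' Sums the abundances of all taxa sharing the same lineage prefix up to
#' `level`, conserving per-sample totals exactly. Taxa with a missing label at
#' `level` are assigned to an explicit `unclassified-<parent>` bin named after
#' the nearest labelled ancestor (never silently dropped). The collapsed
#' table's taxon ids are the full lineage paths up to `level`, which keeps
#' homonymous labels under different parents distinct, and its lineage table
#' retains the ranks down to `level`, so collapsing is composable:
#' genus -> family -> class equals genus -> class.
#'
#' @param x an [AbundanceTable-class] with lineages populated at `level`.
#' @param level one of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return a collapsed [AbundanceTable-class].
#' @examples
#' at <- generateCohort(cohortSpec(nSubjects = 5, sites = "Stool",
#'                                 taxonomyCounts = c(2, 3, 4, 6, 12),
#'                                 poolSize = 10, readDepth = 500), seed = 1)
#' collapseToLevel(at, "phylum")
#' @export
collapseToLevel <- function(x, level = c("phylum", "class", "order",
                                         "family", "genus")) {
  level <- match.arg(level)
  depth <- match(level, .TAXON_RANKS)
  lin <- as.data.frame(lineages(x))
  have <- colnames(lin)
  if (!all(.TAXON_RANKS[seq_len(depth)] %in% have))
    stop("lineages are not populated down to '", level, "'")
  lin <- lin[, .TAXON_RANKS[seq_len(depth)], drop = FALSE]

  ## fill missing labels with unclassified-<nearest labelled ancestor>
  for (k in seq_len(depth)) {
    bad <- is.na(lin[[k]]) | lin[[k]] == ""
    if (any(bad)) {
      parent <- if (k == 1L) rep("root", nrow(lin)) else lin[[k - 1L]]
      lin[[k]][bad] <- paste0("unclassified-", parent[bad])
    }
  }
  key <- do.call(paste, c(lin, sep = ";"))

  m <- assay(x, "counts")
  collapsed <- rowsum(m, group = key, reorder = FALSE)
  keyOrder <- rownames(collapsed)
  rd <- lin[match(keyOrder, key), , drop = FALSE]

  ## taxon id = label at `level`; fall back to the full lineage path when the
  ## same label occurs under different parents
  ids <- rd[[depth]]
  dup <- ids %in% ids[duplicated(ids)]
  ids[dup] <- keyOrder[dup]
  rownames(collapsed) <- ids
  rownames(rd) <- ids

  se <- SummarizedExperiment(
    assays = SimpleList(counts = collapsed),
    rowData = DataFrame(rd),
    colData = colData(x)
  )
  out <- new("AbundanceTable", se)
  metadata(out) <- metadata(x)
  out
}
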