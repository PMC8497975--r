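# Shared fixtures, all built in code.

# A hand-written 4-taxon x 6-sample table over two sites with full lineages.
toyTable <- function() {
  m <- matrix(c(3, 5, 0, 2,
                1, 0, 4, 6,
                2, 2, 2, 2,
                0, 7, 1, 0,
                5, 0, 0, 3,
                4, 1, 3, 2),
              nrow = 4,
              dimnames = list(paste0("G", 1:4), paste0("s", 1:6)))
  lin <- data.frame(
    phylum = c("P1", "P1", "P2", "P2"),
    class  = c("C1", "C1", "C2", "C3"),
    order  = c("O1", "O1", "O2", "O3"),
    family = c("F1", "F1", "F2", "F3"),
    genus  = paste0("G", 1:4),
    row.names = paste0("G", 1:4))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     subject_id = rep(paste0("u", 1:3), 2),
                     site = rep(c("Stool", "TD"), each = 3))
  AbundanceTable(m, meta, lineages = lin)
}

# A small seeded synthetic cohort for pipeline-level tests.
smallCohort <- function(seed, nSubjects = 12, sites = c("A", "B"),
                        poolSize = 30, occupancyBeta = c(1, 4),
                        lognormalSigma = 1, readDepth = 2000,
                        taxonomyCounts = c(3, 5, 8, 15, 60),
                        poolOverlap = 0.5) {
  generateCohort(cohortSpec(nSubjects = nSubjects, sites = sites,
                            taxonomyCounts = taxonomyCounts,
                            poolSize = poolSize, poolOverlap = poolOverlap,
                            occupancyBeta = occupancyBeta,
                            lognormalSigma = lognormalSigma,
                            readDepth = readDepth),
                 seed = seed)
}

# Merge two single-site cohorts into one table with group sites GA/GB,
# padding to the union of their taxa.
mergeAsGroups <- function(a1, a2) {
  n1 <- ncol(a1); n2 <- ncol(a2)
  taxa <- union(rownames(a1), rownames(a2))
  M <- matrix(0, length(taxa), n1 + n2,
              dimnames = list(taxa, c(paste0("A", seq_len(n1)),
                                      paste0("B", seq_len(n2)))))
  M[rownames(a1), seq_len(n1)] <- assay(a1, "counts")
  M[rownames(a2), n1 + seq_len(n2)] <- assay(a2, "counts")
  meta <- data.frame(sample_id = colnames(M), subject_id = colnames(M),
                     site = rep(c("GA", "GB"), c(n1, n2)))
  AbundanceTable(M, meta)
}

# An exact model curve D = c * A^z * exp(d*A) as an AccrualCurve.
modelCurve <- function(n, c0, z, d = 0, q = 0) {
  A <- seq_len(n)
  new("AccrualCurve", areas = A,
      diversities = c0 * A^z * exp(d * A), q = q)
}
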