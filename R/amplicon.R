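## 16S community phenotype profiling: copy-number renormalization, ASV ->
## reference mapping, Phenotype Indices, CPI and prediction error.

asAbundanceMatrix <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  if (is.null(colnames(x)) || is.null(rownames(x)))
    stop("abundance table needs sample rownames and ASV colnames")
  x
}

#' Renormalize ASV relative abundances by 16S copy number
#'
#' Divides each ASV's relative abundance by its 16S rRNA gene copy number
#' and restores per-sample sums to 1: `A'_i = (A_i / c_i) / sum_j (A_j /
#' c_j)`. Converts read-fraction abundances into cell-fraction abundances,
#' which is the scale on which Community Phenotype Indices are interpreted.
#'
#' @param abundance numeric matrix, samples x ASVs, each row summing to 1.
#' @param copies named numeric vector of copy numbers (>= 1). ASVs missing
#'   from `copies` default to 1 (reported via `message`).
#' @return Renormalized abundance matrix of the same shape.
#' @export
#' @examples
#' a <- matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("x", "y")))
#' renormalizeByCopyNumber(a, c(x = 1, y = 4))  # 0.8, 0.2
renormalizeByCopyNumber <- function(abundance, copies) {
  abundance <- asAbundanceMatrix(abundance)
  cvec <- rep(1, ncol(abundance))
  names(cvec) <- colnames(abundance)
  known <- intersect(names(copies), names(cvec))
  cvec[known] <- copies[known]
  missing <- setdiff(names(cvec), names(copies))
  if (length(missing))
    message(length(missing),
            " ASV(s) without a copy number; defaulting to 1")
  if (any(cvec <= 0)) stop("copy numbers must be positive")
  adj <- sweep(abundance, 2L, cvec, "/")
  sums <- rowSums(adj)
  if (any(sums <= 0)) stop("sample with zero total abundance")
  sweep(adj, 1L, sums, "/")
}

## ACGTN scoring: unit match/mismatch, N never matches anything (incl. N)
nucScoringMatrix <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
}

## percent identities of each query against each reference, semi-global:
## the query (amplicon fragment) aligns end-to-end against a substring of
## the reference gene, so spuriously short perfect overlaps cannot occur;
## identity = matches / alignment length, N never counted as a match
identityMatrix <- function(queries, refs, gapOpening = 0, gapExtension = 1) {
  submat <- nucScoringMatrix()
  out <- matrix(NA_real_, length(queries), length(refs),
                dimnames = list(names(queries), names(refs)))
  nonempty <- Biostrings::width(queries) > 0L
  if (!any(nonempty)) return(out)
  q <- queries[nonempty]
  hasN <- Biostrings::alphabetFrequency(q)[, "N"] > 0L
  refN <- Biostrings::alphabetFrequency(refs)[, "N"] > 0L
  for (j in seq_along(refs)) {
    aln <- Biostrings::pairwiseAlignment(
      q, refs[[j]], type = "global-local", substitutionMatrix = submat,
      gapOpening = gapOpening, gapExtension = gapExtension)
    indel <- Biostrings::nindel(aln)
    len <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
      Biostrings::insertion(indel)[, "WidthSum"] +
      Biostrings::deletion(indel)[, "WidthSum"]
    id <- ifelse(len > 0, 100 * Biostrings::nmatch(aln) / len, 0)
    ## N never counts as a match; recount affected pairs by character
    redo <- which(hasN | refN[j])
    for (k in redo) {
      p <- strsplit(as.character(Biostrings::alignedPattern(aln[k])), "")[[1L]]
      s <- strsplit(as.character(Biostrings::alignedSubject(aln[k])), "")[[1L]]
      id[k] <- if (!length(p)) 0
               else 100 * sum(p == s & p %in% c("A", "C", "G", "T")) / length(p)
    }
    out[nonempty, j] <- id
  }
  out
}

#' Map ASV sequences to reference 16S sequences
#'
#' Aligns every ASV against every reference 16S sequence (semi-global:
#' the ASV aligns end-to-end against a substring of the reference, as an
#' amplicon is a fragment of the gene) and retains all hits whose percent
#' identity (matches over alignment length; `N` never matches) reaches the
#' threshold. The default 90% threshold corresponds roughly to family-level
#' taxonomic resolution; ASVs with no hit at the threshold are unmapped and
#' excluded downstream.
#'
#' @param asvSeqs ASV sequences: named [Biostrings::DNAStringSet] or named
#'   character vector.
#' @param refSeqs reference 16S sequences, named by genome id.
#' @param identity percent-identity threshold (default 90).
#' @param gapOpening,gapExtension alignment gap costs (unit costs by
#'   default).
#' @return An [AsvMapping-class].
#' @export
mapAsvs <- function(asvSeqs, refSeqs, identity = 90,
                    gapOpening = 0, gapExtension = 1) {
  if (!is(asvSeqs, "DNAStringSet")) asvSeqs <- Biostrings::DNAStringSet(asvSeqs)
  if (!is(refSeqs, "DNAStringSet")) refSeqs <- Biostrings::DNAStringSet(refSeqs)
  if (!length(refSeqs)) stop("empty reference sequence set")
  if (is.null(names(asvSeqs)) || is.null(names(refSeqs)))
    stop("ASV and reference sequences must be named")
  empty <- Biostrings::width(asvSeqs) == 0L
  if (any(empty))
    warning("empty ASV sequence(s) left unmapped: ",
            paste(names(asvSeqs)[empty], collapse = ", "))
  idm <- identityMatrix(asvSeqs, refSeqs, gapOpening, gapExtension)
  hit <- which(!is.na(idm) & idm >= identity, arr.ind = TRUE)
  hits <- data.frame(
    asv_id = rownames(idm)[hit[, 1L]],
    genome_id = colnames(idm)[hit[, 2L]],
    identity = idm[hit],
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$asv_id, hits$genome_id), , drop = FALSE]
  rownames(hits) <- NULL
  new("AsvMapping", hits = hits, asvIds = names(asvSeqs),
      threshold = identity)
}

#' Precomputed ASV mapping from a hit table
#'
#' Builds an [AsvMapping-class] from an externally computed hit table
#' (e.g. from a dedicated search tool), bypassing alignment. Hits below
#' the threshold are dropped.
#'
#' @param hits data.frame with columns `asv_id`, `genome_id`, `identity`.
#' @param asv_ids all query ASV ids (defaults to those present in `hits`).
#' @param identity percent-identity threshold.
#' @return An [AsvMapping-class].
#' @export
asvMappingFromHits <- function(hits, asv_ids = unique(hits$asv_id),
                               identity = 90) {
  hits <- hits[hits$identity >= identity, , drop = FALSE]
  rownames(hits) <- NULL
  new("AsvMapping", hits = hits, asvIds = as.character(asv_ids),
      threshold = identity)
}

#' Phenotype Indices for mapped ASVs
#'
#' The Phenotype Index of an ASV is the unweighted mean of the binary
#' phenotype over all reference genomes the ASV mapped to, a probability
#' in `[0, 1]` that the ASV is a phenotype carrier. Unmapped ASVs get `NA`
#' rows.
#'
#' @param mapping an [AsvMapping-class].
#' @param bpm a [BinaryPhenotypeMatrix-class] covering all mapped genomes.
#' @return Numeric matrix ASVs x phenotypes with values in `[0, 1]`.
#' @export
computePhenotypeIndices <- function(mapping, bpm) {
  stopifnot(is(mapping, "AsvMapping"), is(bpm, "BinaryPhenotypeMatrix"))
  hits <- mappingHits(mapping)
  missing <- setdiff(unique(hits$genome_id), genomeIds(bpm))
  if (length(missing))
    stop("mapped genome(s) absent from BPM: ",
         paste(missing, collapse = ", "))
  ph <- phenotypeMatrix(bpm)
  out <- matrix(NA_real_, length(mapping@asvIds), ncol(ph),
                dimnames = list(mapping@asvIds, colnames(ph)))
  for (asv in unique(hits$asv_id)) {
    g <- hits$genome_id[hits$asv_id == asv]
    out[asv, ] <- colMeans(ph[g, , drop = FALSE])
  }
  out
}

#' Coverage filtering and renormalization of mapped abundances
#'
#' Per-sample coverage is the total relative abundance of mapped ASVs
#' (before any renormalization). Samples below the coverage threshold are
#' flagged discarded; for retained samples the mapped abundances are
#' renormalized to sum to 1. The boundary is inclusive: coverage exactly
#' at the threshold is retained.
#'
#' @param abundance samples x ASVs relative abundance matrix.
#' @param mapping an [AsvMapping-class].
#' @param coverage coverage threshold in `[0, 1]` (default 0.75).
#' @return List: `abundance` (samples x mapped ASVs, renormalized; rows of
#'   discarded or zero-coverage samples are `NA`), `coverage` (named
#'   numeric), `retained` (named logical).
#' @export
filterAndRenormalize <- function(abundance, mapping, coverage = 0.75) {
  abundance <- asAbundanceMatrix(abundance)
  stopifnot(is(mapping, "AsvMapping"))
  mapped <- intersect(colnames(abundance), mappedAsvs(mapping))
  cov <- rowSums(abundance[, mapped, drop = FALSE])
  retained <- cov >= coverage
  renorm <- abundance[, mapped, drop = FALSE]
  for (i in seq_len(nrow(renorm))) {
    if (retained[i] && cov[i] > 0) renorm[i, ] <- renorm[i, ] / cov[i]
    else renorm[i, ] <- NA_real_
  }
  list(abundance = renorm, coverage = cov, retained = retained)
}

#' Community Phenotype Index
#'
#' `CPI = sum_i A_i PI_i` per sample and phenotype: the expected fraction
#' of the community's bacterial cells carrying the metabolic capability.
#'
#' @param abundance samples x ASVs matrix, rows summing to 1 (`NA` rows
#'   propagate to `NA` CPIs).
#' @param pis ASVs x phenotypes Phenotype Index matrix covering every ASV
#'   column of `abundance`.
#' @return Numeric matrix samples x phenotypes.
#' @export
computeCpi <- function(abundance, pis) {
  abundance <- as.matrix(abundance)
  pis <- as.matrix(pis)
  if (!all(colnames(abundance) %in% rownames(pis)))
    stop("ASV(s) without a Phenotype Index: ",
         paste(setdiff(colnames(abundance), rownames(pis)), collapse = ", "))
  pim <- pis[colnames(abundance), , drop = FALSE]
  if (anyNA(pim))
    stop("Phenotype Index is NA for an ASV carried into CPI computation")
  abundance %*% pim
}

#' CPI prediction error
#'
#' The prediction variance `v = sum_i A_i^2 PI_i (1 - PI_i)` reflects
#' imprecise mapping and phenotype microheterogeneity among the mapped
#' genomes; it vanishes exactly when every Phenotype Index is binary. The
#' reported error is `sigma = sqrt(v)` (on the CPI scale) by default.
#'
#' @inheritParams computeCpi
#' @param mode `"sqrt"` (default) returns `sqrt(v)`; `"raw"` returns the
#'   plain sum `v`.
#' @return Numeric matrix samples x phenotypes.
#' @export
computeCpiError <- function(abundance, pis, mode = c("sqrt", "raw")) {
  mode <- match.arg(mode)
  abundance <- as.matrix(abundance)
  pis <- as.matrix(pis)
  if (!all(colnames(abundance) %in% rownames(pis)))
    stop("ASV(s) without a Phenotype Index")
  pim <- pis[colnames(abundance), , drop = FALSE]
  v <- (abundance^2) %*% (pim * (1 - pim))
  if (mode == "sqrt") sqrt(v) else v
}

#' End-to-end 16S phenotype profiling
#'
#' Runs the full amplicon pipeline: copy-number renormalization, sequence
#' mapping to the reference 16S set, Phenotype Index assignment, coverage
#' filtering with renormalization of mapped abundances, and CPI / error
#' computation.
#'
#' @param abundance samples x ASVs relative abundance matrix (rows sum
#'   to 1).
#' @param asvSeqs,refSeqs named DNA sequences, see [mapAsvs()].
#' @param bpm a [BinaryPhenotypeMatrix-class].
#' @param copies optional named 16S copy-number vector (default: all 1,
#'   i.e. no correction).
#' @param identity percent-identity mapping threshold (default 90).
#' @param coverage minimum mapped-abundance coverage to retain a sample
#'   (default 0.75, inclusive).
#' @param mapping optionally a precomputed [AsvMapping-class]; skips
#'   alignment.
#' @return List: `profile` (a [CpiProfile-class]), `pi` (Phenotype Index
#'   matrix), `mapping` (the [AsvMapping-class]), `abundance` (the
#'   filtered, renormalized matrix actually used).
#' @export
profile16S <- function(abundance, asvSeqs, refSeqs, bpm, copies = NULL,
                       identity = 90, coverage = 0.75, mapping = NULL) {
  abundance <- asAbundanceMatrix(abundance)
  if (!is.null(copies))
    abundance <- renormalizeByCopyNumber(abundance, copies)
  if (is.null(mapping))
    mapping <- mapAsvs(asvSeqs, refSeqs, identity = identity)
  pis <- computePhenotypeIndices(mapping, bpm)
  flt <- filterAndRenormalize(abundance, mapping, coverage = coverage)
  ab <- flt$abundance
  usable <- flt$retained & flt$coverage > 0
  cpim <- matrix(NA_real_, nrow(abundance), ncol(pis),
                 dimnames = list(rownames(abundance), colnames(pis)))
  varm <- cpim
  if (any(usable) && ncol(ab)) {
    sub <- ab[usable, , drop = FALSE]
    cpim[usable, ] <- computeCpi(sub, pis)
    varm[usable, ] <- computeCpiError(sub, pis, mode = "raw")
  }
  profile <- new("CpiProfile", cpi = cpim, sigma = sqrt(varm),
                 variance = varm, coverage = flt$coverage,
                 retained = flt$retained)
  list(profile = profile, pi = pis, mapping = mapping, abundance = ab)
}
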