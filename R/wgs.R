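## WGS-side profiling: taxonomy-based CPI and core-gene-referenced
## TMM-normalized pathway abundances.

#' Map taxon abundance profiles to the BPM and compute CPI
#'
#' For each taxon (given as a seven-rank path, `"undefined"` below the
#' known rank), finds the reference genomes sharing its deepest defined
#' rank, provided that rank is family or better. Taxa matching only above
#' family level (or not at all) are non-mapped and discarded, with mapped
#' abundances renormalized to sum to 1. Phenotype Indices are phenotype
#' means over the matched genomes; CPI and error follow the amplicon-side
#' formulas, so identical abundance/PI inputs give identical CPI either
#' way.
#'
#' @param abundance samples x taxa relative abundance matrix (rows sum
#'   to 1).
#' @param taxa data.frame of seven-rank labels (rownames = taxon ids,
#'   columns [taxonomyRanks()]) describing each abundance column.
#' @param bpm a [BinaryPhenotypeMatrix-class].
#' @param worstRank coarsest acceptable matching rank (default
#'   `"family"`).
#' @return List: `profile` (a [CpiProfile-class]; samples with no mapped
#'   taxon are flagged not retained), `pi` (taxa x phenotypes), `mapped`
#'   (named logical per taxon).
#' @export
taxonomyMapCpi <- function(abundance, taxa, bpm, worstRank = "family") {
  abundance <- asAbundanceMatrix(abundance)
  stopifnot(is(bpm, "BinaryPhenotypeMatrix"))
  ranks <- taxonomyRanks()
  if (!worstRank %in% ranks) stop("unknown rank: ", worstRank)
  if (!identical(colnames(taxa), ranks))
    stop("taxon rank paths malformed: need the seven rank columns")
  if (!all(colnames(abundance) %in% rownames(taxa)))
    stop("taxon rank paths malformed: missing taxa")
  taxa <- taxa[colnames(abundance), , drop = FALSE]
  refTx <- taxonomy(bpm)
  ph <- phenotypeMatrix(bpm)
  worstIdx <- match(worstRank, ranks)

  pis <- matrix(NA_real_, ncol(abundance), ncol(ph),
                dimnames = list(colnames(abundance), colnames(ph)))
  for (t in rownames(taxa)) {
    path <- as.character(taxa[t, ])
    defined <- which(path != "undefined")
    ## deepest defined rank with reference matches; mapped only if that
    ## rank is at least as fine as worstRank
    for (r in rev(defined)) {
      candidates <- rep(TRUE, nrow(refTx))
      for (k in seq_len(r)) candidates <- candidates & (refTx[[k]] == path[k])
      if (any(candidates)) {
        if (r >= worstIdx)
          pis[t, ] <- colMeans(ph[candidates, , drop = FALSE])
        break
      }
    }
  }
  mapped <- !is.na(pis[, 1L])
  cov <- rowSums(abundance[, mapped, drop = FALSE])
  retained <- cov > 0
  renorm <- abundance[, mapped, drop = FALSE]
  cpim <- matrix(NA_real_, nrow(abundance), ncol(ph),
                 dimnames = list(rownames(abundance), colnames(ph)))
  varm <- cpim
  if (any(retained) && any(mapped)) {
    sub <- sweep(renorm[retained, , drop = FALSE], 1L, cov[retained], "/")
    cpim[retained, ] <- computeCpi(sub, pis[mapped, , drop = FALSE])
    varm[retained, ] <- computeCpiError(sub, pis[mapped, , drop = FALSE],
                                        mode = "raw")
  }
  profile <- new("CpiProfile", cpi = cpim, sigma = sqrt(varm),
                 variance = varm, coverage = cov, retained = retained)
  list(profile = profile, pi = pis, mapped = mapped)
}

#' TMM scaling factors referenced to a core gene set
#'
#' Trimmed-mean-of-M-values normalization factors computed from the rows
#' of a designated set of universal single-copy core genes (present in all
#' reference genomes), so that pathway-gene signal never influences the
#' normalization. The reference sample is the one whose core-gene
#' counts-per-million upper quartile is closest to the mean (configurable).
#' Per gene, `M` is the log2 ratio of library-size-normalized counts
#' against the reference and `A` the mean log2 abundance; genes in the
#' top/bottom `trimM` fraction by M or `trimA` fraction by A are trimmed,
#' and the factor is 2 to the inverse-variance-weighted mean of the
#' remaining M values. Factors are rescaled to geometric mean 1.
#'
#' @param counts non-negative integer matrix, functional roles x samples.
#' @param coreGenes character vector of core-gene row names.
#' @param trimM,trimA tail fractions trimmed by M and by A (defaults 0.30
#'   and 0.05, the standard published values).
#' @param ref optional sample id to force as reference.
#' @param libSizes library sizes; defaults to full column sums of
#'   `counts`.
#' @return Named numeric vector of scaling factors, geometric mean 1.
#' @export
tmmFactors <- function(counts, coreGenes, trimM = 0.30, trimA = 0.05,
                       ref = NULL, libSizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  if (!length(coreGenes)) stop("empty core gene set")
  missing <- setdiff(coreGenes, rownames(counts))
  if (length(missing))
    stop("core gene(s) absent from count table: ",
         paste(missing, collapse = ", "))
  core <- counts[coreGenes, , drop = FALSE]
  if (any(colSums(core) == 0))
    stop("sample(s) with zero total core-gene counts: ",
         paste(colnames(core)[colSums(core) == 0], collapse = ", "))
  cpm <- sweep(core, 2L, libSizes, "/") * 1e6
  if (is.null(ref)) {
    uq <- apply(cpm, 2L, stats::quantile, probs = 0.75)
    ref <- colnames(core)[which.min(abs(uq - mean(uq)))]
  }
  stopifnot(ref %in% colnames(core))
  refC <- core[, ref]
  nR <- libSizes[ref]
  f <- vapply(colnames(core), function(s) {
    if (s == ref) return(1)
    obs <- core[, s]
    nO <- libSizes[s]
    keep <- obs > 0 & refC > 0     # log-ratio undefined otherwise
    if (!any(keep)) return(1)
    o <- obs[keep]; r <- refC[keep]
    pO <- o / nO; pR <- r / nR
    M <- log2(pO / pR)
    A <- 0.5 * log2(pO * pR)
    ## inverse approximate-variance weights on relative counts, so factors
    ## are exactly invariant to per-sample count scaling
    w <- (1 - pO) / pO + (1 - pR) / pR
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(sel) || all(w[sel] == 0)) return(1)
    2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }, 0)
  f / exp(mean(log(f)))
}

#' Apply normalization factors to a count table
#'
#' Scales each count to counts-per-million of its effective library
#' (library size times TMM factor): `CPM = 1e6 * count / (libSize *
#' factor)`. Doubling every count of a sample leaves its CPMs unchanged.
#'
#' @param counts functional roles x samples count matrix.
#' @param factors named factors from [tmmFactors()].
#' @param libSizes library sizes (default: column sums).
#' @return Numeric matrix of normalized abundances (CPM).
#' @export
normalizeCounts <- function(counts, factors, libSizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (!all(colnames(counts) %in% names(factors)))
    stop("missing normalization factor for sample(s): ",
         paste(setdiff(colnames(counts), names(factors)), collapse = ", "))
  if (any(libSizes <= 0)) stop("zero library size")
  eff <- libSizes * factors[colnames(counts)]
  sweep(counts, 2L, eff, "/") * 1e6
}

#' Variant-specific pathway gene signatures
#'
#' For each product, the signature of a variant is the set of roles
#' appearing in that variant and in no other variant of the same product;
#' roles of shared segments (e.g. the universal butyrate crotonyl-CoA to
#' butyryl-CoA step and the terminal release transferases) are excluded
#' from variant signatures and reported as their own named entries. This
#' prevents double counting when per-variant abundances are summed.
#'
#' @param pathways a [PathwaySet-class].
#' @return Named list per product; each element a named list of role-id
#'   vectors (one per variant plus one per shared segment).
#' @export
pathwaySignatures <- function(pathways) {
  stopifnot(is(pathways, "PathwaySet"))
  defRoles <- function(groups) unique(unlist(lapply(groups, `[[`,
                                                    "alternatives")))
  prods <- pathwayProducts(pathways)
  out <- stats::setNames(vector("list", length(prods)), prods)
  for (p in prods) {
    defs <- Filter(function(d) d$product == p, pathways@definitions)
    sharedRoles <- unique(unlist(lapply(pathways@shared[[p]], defRoles)))
    own <- lapply(defs, function(d) setdiff(defRoles(d$groups), sharedRoles))
    names(own) <- vapply(defs, `[[`, "", "label")
    counts <- table(unlist(own))
    uniq <- names(counts)[counts == 1L]
    sig <- lapply(own, function(r) intersect(r, uniq))
    for (seg in names(pathways@shared[[p]]))
      sig[[seg]] <- defRoles(pathways@shared[[p]][[seg]])
    out[[p]] <- sig
  }
  out
}

#' Pathway abundances from normalized gene counts
#'
#' Sums normalized gene abundances over each signature's roles, per sample
#' and per (product, variant-or-segment) entry. Signature roles absent
#' from the table are treated as zero with a warning.
#'
#' @param normalized roles x samples normalized abundance matrix, e.g.
#'   from [normalizeCounts()].
#' @param signatures output of [pathwaySignatures()], or a compatible
#'   nested list.
#' @return Numeric matrix samples x entries; columns named
#'   `"<product>.<variant>"`.
#' @export
pathwayAbundance <- function(normalized, signatures) {
  normalized <- as.matrix(normalized)
  entries <- list()
  for (p in names(signatures)) {
    for (v in names(signatures[[p]])) {
      roles <- signatures[[p]][[v]]
      if (!length(roles))
        stop(sprintf("empty signature for %s/%s", p, v))
      absent <- setdiff(roles, rownames(normalized))
      if (length(absent))
        warning(sprintf("signature role(s) absent, treated as 0: %s",
                        paste(absent, collapse = ", ")))
      present <- intersect(roles, rownames(normalized))
      entries[[paste(p, v, sep = ".")]] <-
        if (length(present)) colSums(normalized[present, , drop = FALSE])
        else stats::setNames(numeric(ncol(normalized)), colnames(normalized))
    }
  }
  do.call(cbind, entries)
}

#' Rank correlation between CPI and pathway abundances
#'
#' Spearman correlations (ties mid-ranked) across shared samples between
#' each phenotype's CPI and each pathway-abundance entry of the same
#' product.
#'
#' @param profile a [CpiProfile-class] or a samples x phenotypes CPI
#'   matrix.
#' @param abundances samples x entries matrix from [pathwayAbundance()].
#' @return data.frame with columns `phenotype`, `entry`, `rho`.
#' @export
cpiPathwayCorrelation <- function(profile, abundances) {
  cpim <- if (is(profile, "CpiProfile")) cpi(profile) else as.matrix(profile)
  shared <- intersect(rownames(cpim), rownames(abundances))
  if (length(shared) < 3L)
    stop("need at least 3 shared samples for rank correlation")
  cpim <- cpim[shared, , drop = FALSE]
  ab <- abundances[shared, , drop = FALSE]
  rows <- list()
  for (ph in colnames(cpim)) {
    cols <- grep(paste0("^", ph, "\\."), colnames(ab), value = TRUE)
    for (cl in cols) {
      ok <- stats::complete.cases(cpim[, ph], ab[, cl])
      if (sum(ok) < 3L) next
      rows[[paste(ph, cl)]] <- data.frame(
        phenotype = ph, entry = cl,
        rho = stats::cor(cpim[ok, ph], ab[ok, cl], method = "spearman"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
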