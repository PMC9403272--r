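## Phenotype variability within taxonomic groups: NVP and OPVS.

#' Per-phenotype variability score
#'
#' Score of a producer fraction `p` within a taxonomic group. The default
#' (`"gini"`) is the Gini impurity `2 p (1 - p)`: it is 0 exactly when the
#' group is phenotype-homogeneous and attains its maximum 0.5 at `p = 0.5`
#' (equal numbers of producers and non-producers) for groups of any size,
#' so the six-phenotype sum (OPVS) is bounded by 3. Population variance
#' `p (1 - p)` and the unbiased sample variance are available for
#' sensitivity checks.
#'
#' @param p producer fraction(s) in `[0, 1]`.
#' @param mode `"gini"` (default), `"population"` or `"sample"`.
#' @param n group size; required for `mode = "sample"`.
#' @return Numeric score(s); for `"gini"`, in `[0, 0.5]`.
#' @export
#' @examples
#' variabilityScore(0.5)   # 0.5
#' variabilityScore(0.25)  # 0.375
variabilityScore <- function(p, mode = c("gini", "population", "sample"),
                             n = NULL) {
  mode <- match.arg(mode)
  if (any(p < 0 | p > 1)) stop("producer fraction outside [0, 1]")
  switch(mode,
    gini = 2 * p * (1 - p),
    population = p * (1 - p),
    sample = {
      if (is.null(n)) stop("mode 'sample' needs the group size n")
      if (n < 2) 0 * p else n / (n - 1) * p * (1 - p)
    })
}

#' Variability report for one taxonomic group
#'
#' Given the phenotype rows of the group's member genomes, computes per
#' phenotype the producer fraction and variability score, the number of
#' variable phenotypes (NVP: phenotypes with `0 < p < 1`) and the overall
#' phenotype variability score (OPVS: sum of the six scores, in `[0, 3]`
#' for the default score).
#'
#' @param members 0/1 matrix (members x phenotypes) or a
#'   [BinaryPhenotypeMatrix-class] restricted to the group's genomes.
#' @param mode score definition, see [variabilityScore()].
#' @return List with `fraction` and `score` (named numeric vectors over
#'   phenotypes), `nvp` (integer) and `opvs` (numeric).
#' @export
#' @examples
#' m <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 1, 0, 0, 1))
#' colnames(m) <- scfaPhenotypes()
#' groupVariability(m)$opvs  # 1.5
groupVariability <- function(members, mode = "gini") {
  if (is(members, "BinaryPhenotypeMatrix")) members <- phenotypeMatrix(members)
  members <- as.matrix(members)
  if (!nrow(members)) stop("empty taxonomic group")
  p <- colMeans(members)
  s <- variabilityScore(p, mode = mode, n = nrow(members))
  list(fraction = p, score = s,
       nvp = sum(p > 0 & p < 1), opvs = sum(s))
}

#' Rank taxonomic groups by phenotype variability
#'
#' Groups genomes of a BPM by species or genus label, drops singleton
#' groups and groups with `"undefined"` labels, filters by NVP/OPVS
#' thresholds, and ranks by OPVS (descending; alphabetical tie-break).
#'
#' @param bpm a [BinaryPhenotypeMatrix-class] with taxonomy.
#' @param rank `"species"` or `"genus"`.
#' @param nvp_min,opvs_min inclusive lower thresholds.
#' @param mode score definition, see [variabilityScore()].
#' @return data.frame with columns `group`, `n_members`, `nvp`, `opvs`,
#'   `family`, `phylum`, ordered by decreasing OPVS.
#' @export
rankVariableGroups <- function(bpm, rank = c("species", "genus"),
                               nvp_min = 0, opvs_min = 0, mode = "gini") {
  rank <- match.arg(rank)
  stopifnot(is(bpm, "BinaryPhenotypeMatrix"))
  tx <- taxonomy(bpm)
  labels <- tx[[rank]]
  keep <- labels != "undefined"
  idx <- split(which(keep), labels[keep])
  idx <- idx[vapply(idx, length, 0L) > 1L]
  if (!length(idx))
    return(data.frame(group = character(), n_members = integer(),
                      nvp = integer(), opvs = numeric(),
                      family = character(), phylum = character(),
                      stringsAsFactors = FALSE))
  ph <- phenotypeMatrix(bpm)
  rows <- lapply(names(idx), function(g) {
    i <- idx[[g]]
    rep_ <- groupVariability(ph[i, , drop = FALSE], mode = mode)
    data.frame(group = g, n_members = length(i), nvp = rep_$nvp,
               opvs = rep_$opvs, family = tx$family[i[1L]],
               phylum = tx$phylum[i[1L]], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$nvp >= nvp_min & res$opvs >= opvs_min, , drop = FALSE]
  res <- res[order(-res$opvs, res$group), , drop = FALSE]
  rownames(res) <- NULL
  res
}
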