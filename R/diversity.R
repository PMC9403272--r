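## Alpha/beta diversity and phenotype beta diversity of carrier
## sub-communities.

checkTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in tree")
  tree
}

## per-edge abundance fraction descending through each branch: value at the
## child node of every edge, accumulated tips-up
edgeAbundance <- function(tree, abundance) {
  ntip <- length(tree$tip.label)
  val <- numeric(ntip + tree$Nnode)
  val[seq_len(ntip)] <- abundance[tree$tip.label]
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge)))
    val[po$edge[i, 1L]] <- val[po$edge[i, 1L]] + val[po$edge[i, 2L]]
  val[tree$edge[, 2L]]
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning the observed
#' leaves and the root (root-to-subtree branches included). Monotone under
#' adding observed leaves; equals the total branch length when all leaves
#' are observed.
#'
#' @param observed character vector of observed leaf names.
#' @param tree rooted `phylo` tree with non-negative branch lengths.
#' @return Numeric alpha-diversity value.
#' @export
faithPd <- function(observed, tree) {
  checkTree(tree)
  observed <- unique(as.character(observed))
  bad <- setdiff(observed, tree$tip.label)
  if (length(bad))
    stop("observed leaf absent from tree: ", paste(bad, collapse = ", "))
  if (!length(observed)) return(0)
  ind <- stats::setNames(as.numeric(tree$tip.label %in% observed),
                         tree$tip.label)
  sum(tree$edge.length[edgeAbundance(tree, ind) > 0])
}

#' Weighted UniFrac distance
#'
#' Normalized weighted UniFrac between two abundance profiles on a shared
#' tree: `sum_l b_l |pA(l) - pB(l)| / sum_l b_l (pA(l) + pB(l))`, where
#' `pX(l)` is the abundance fraction descending through branch `l`.
#' Symmetric, 0 for identical profiles, bounded by 1. The raw
#' (unnormalized) numerator is available via `normalized = FALSE`.
#'
#' @param a,b named abundance vectors over tree leaves, each summing to 1
#'   (leaves absent from a vector count as 0).
#' @param tree rooted `phylo` tree with non-negative branch lengths.
#' @param normalized logical, default `TRUE`.
#' @return Numeric distance.
#' @export
weightedUnifrac <- function(a, b, tree, normalized = TRUE) {
  checkTree(tree)
  fill <- function(x) {
    v <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
    x <- x[!is.na(x)]
    bad <- setdiff(names(x), tree$tip.label)
    if (length(bad))
      stop("leaf absent from tree: ", paste(bad, collapse = ", "))
    v[names(x)] <- x
    if (sum(v) <= 0) stop("empty sample in weighted UniFrac")
    v / sum(v)
  }
  pa <- edgeAbundance(tree, fill(a))
  pb <- edgeAbundance(tree, fill(b))
  num <- sum(tree$edge.length * abs(pa - pb))
  if (!normalized) return(num)
  den <- sum(tree$edge.length * (pa + pb))
  if (den == 0) return(0)
  num / den
}

#' Carrier sub-communities of a phenotype
#'
#' An ASV is a carrier of a phenotype when its Phenotype Index is at or
#' above the carrier threshold (inclusive; default 0.5). Per sample, the
#' carrier abundances are renormalized to sum to 1; samples whose carrier
#' abundance is zero are flagged empty and excluded from PBD pairs.
#'
#' @param abundance samples x ASVs relative abundance matrix.
#' @param pis ASVs x phenotypes Phenotype Index matrix.
#' @param phenotype phenotype column name.
#' @param threshold carrier threshold on PI (default 0.5, inclusive).
#' @return List: `abundance` (samples x carrier ASVs, renormalized; `NA`
#'   rows for empty sub-communities), `carriers` (character), `empty`
#'   (named logical per sample).
#' @export
carrierSubcommunities <- function(abundance, pis, phenotype,
                                  threshold = 0.5) {
  abundance <- asAbundanceMatrix(abundance)
  piv <- pis[colnames(abundance), phenotype]
  if (anyNA(piv))
    stop("Phenotype Index undefined for ASV(s): ",
         paste(colnames(abundance)[is.na(piv)], collapse = ", "))
  carriers <- colnames(abundance)[piv >= threshold]
  sub <- abundance[, carriers, drop = FALSE]
  tot <- rowSums(sub)
  empty <- tot <= 0
  for (i in seq_len(nrow(sub)))
    sub[i, ] <- if (empty[i]) NA_real_ else sub[i, ] / tot[i]
  list(abundance = sub, carriers = carriers, empty = empty)
}

#' Phenotype beta diversity and its ratio to total beta diversity
#'
#' `PBD(i, j)` is the beta-diversity metric evaluated on the carrier
#' sub-communities of a phenotype; `rPBD(i, j) = PBD(i, j) / BD(i, j)`
#' divides out the whole-community beta diversity to account for diversity
#' scale inheritance. Pairs with an empty carrier sub-community give `NA`
#' PBD; pairs with `BD = 0` give `NA` rPBD. When the carriers are the
#' entire community, `PBD = BD` and `rPBD = 1`.
#'
#' @inheritParams carrierSubcommunities
#' @param tree rooted `phylo` tree covering all ASVs.
#' @param metric distance function `f(a, b, tree)` (default
#'   [weightedUnifrac()]).
#' @return List of symmetric matrices `pbd`, `bd`, `rpbd` (samples x
#'   samples), plus `empty` flags.
#' @export
pbdRpbd <- function(abundance, pis, phenotype, tree, threshold = 0.5,
                    metric = weightedUnifrac) {
  abundance <- asAbundanceMatrix(abundance)
  if (!is.function(metric)) stop("metric unavailable")
  sub <- carrierSubcommunities(abundance, pis, phenotype, threshold)
  n <- nrow(abundance)
  ids <- rownames(abundance)
  bd <- pbd <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    bd[i, j] <- bd[j, i] <- metric(abundance[i, ], abundance[j, ], tree)
    pbd[i, j] <- pbd[j, i] <-
      if (sub$empty[i] || sub$empty[j]) NA_real_
      else metric(sub$abundance[i, ], sub$abundance[j, ], tree)
  }
  rpbd <- pbd / bd
  rpbd[!is.na(bd) & bd == 0] <- NA_real_
  diag(rpbd) <- NA_real_
  list(pbd = pbd, bd = bd, rpbd = rpbd, empty = sub$empty)
}

#' Mean intragroup and intergroup pairwise distances
#'
#' Averages a symmetric distance matrix over unordered within-group and
#' between-group sample pairs (diagonal excluded).
#'
#' @param d symmetric distance matrix with sample dimnames.
#' @param groups group labels, one per sample (named or in matrix order).
#' @return List: `intragroup` and `intergroup` overall means, and
#'   `by_group` per-group intragroup means (`NA` for groups with fewer
#'   than two members).
#' @export
groupDistanceSummary <- function(d, groups) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (length(unique(groups)) < 2L) stop("need at least two groups")
  groups <- rep_len(as.character(groups), nrow(d))
  same <- outer(groups, groups, "==")
  ut <- upper.tri(d)
  by_group <- vapply(unique(groups), function(g) {
    sel <- ut & outer(groups == g, groups == g, "&")
    if (!any(sel)) NA_real_ else mean(d[sel], na.rm = TRUE)
  }, 0)
  list(intragroup = mean(d[ut & same], na.rm = TRUE),
       intergroup = mean(d[ut & !same], na.rm = TRUE),
       by_group = by_group)
}

#' Bin CPI values by alpha diversity
#'
#' Bins samples into equal-width alpha-diversity bins over the observed AD
#' range and summarizes the CPI distribution per bin (median, quartiles,
#' count), the binning behind CPI-vs-AD profiles.
#'
#' @param cpiValues named numeric CPI vector per sample (one phenotype),
#'   or a [CpiProfile-class] with `phenotype` naming the column.
#' @param ad named numeric alpha-diversity vector over the same samples.
#' @param nBins number of bins (>= 1).
#' @param phenotype phenotype column when `cpiValues` is a profile.
#' @return data.frame: `bin`, `ad_lo`, `ad_hi`, `n`, `median`, `q1`, `q3`.
#' @export
cpiVsAdBins <- function(cpiValues, ad, nBins = 10L, phenotype = NULL) {
  if (is(cpiValues, "CpiProfile")) {
    stopifnot(!is.null(phenotype))
    cpiValues <- cpi(cpiValues)[, phenotype]
  }
  if (nBins < 1L) stop("nBins must be at least 1")
  shared <- intersect(names(cpiValues), names(ad))
  if (!length(shared)) stop("no matching sample ids")
  x <- ad[shared]
  y <- cpiValues[shared]
  rng <- range(x)
  breaks <- if (rng[1L] == rng[2L]) c(rng[1L] - 0.5, rng[2L] + 0.5)
            else seq(rng[1L], rng[2L], length.out = nBins + 1L)
  bin <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  rows <- lapply(sort(unique(bin)), function(b) {
    v <- y[bin == b]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(bin = b, ad_lo = breaks[b], ad_hi = breaks[b + 1L],
               n = length(v), median = q[2L], q1 = q[1L], q3 = q[3L])
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
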