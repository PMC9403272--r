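# Independent brute-force oracles and small fixture builders.

# Variant calling by exhaustive enumeration: a variant is complete iff some
# combination of one alternative per required group is fully present.
bruteCallVariants <- function(roles, ps) {
  defs <- ps@definitions
  out <- list()
  for (def in defs) {
    groups <- Filter(function(g) g$required, def$groups)
    complete <- if (!length(groups)) TRUE else {
      idx <- expand.grid(lapply(groups, function(g)
        seq_along(g$alternatives)))
      any(apply(idx, 1L, function(row) {
        need <- unlist(lapply(seq_along(groups), function(k)
          groups[[k]]$alternatives[[row[k]]]))
        all(need %in% roles)
      }))
    }
    if (complete)
      out[[def$product]] <- c(out[[def$product]], def$label)
  }
  lapply(out, sort)
}

stripSub <- function(x) sort(unique(sub("\\*$", "", x)))

# Weighted UniFrac by explicit per-branch descendant enumeration.
bruteUnifrac <- function(a, b, tree, normalized = TRUE) {
  ntip <- length(tree$tip.label)
  descTips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, descTips))
  }
  get <- function(x, tips) sum(x[intersect(names(x), tips)])
  a <- a / sum(a); b <- b / sum(b)
  num <- den <- 0
  for (i in seq_len(nrow(tree$edge))) {
    tips <- descTips(tree$edge[i, 2L])
    pa <- get(a, tips); pb <- get(b, tips)
    num <- num + tree$edge.length[i] * abs(pa - pb)
    den <- den + tree$edge.length[i] * (pa + pb)
  }
  if (!normalized) return(num)
  if (den == 0) 0 else num / den
}

# Faith PD via union of root-to-tip node paths.
bruteFaithPd <- function(observed, tree) {
  root <- length(tree$tip.label) + 1L
  edges <- unique(do.call(rbind, lapply(observed, function(tip) {
    np <- ape::nodepath(tree, from = root, to = match(tip, tree$tip.label))
    cbind(np[-length(np)], np[-1L])
  })))
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  sum(tree$edge.length[key %in% paste(edges[, 1L], edges[, 2L])])
}

bruteCpi <- function(A, PI) {
  out <- matrix(0, nrow(A), ncol(PI),
                dimnames = list(rownames(A), colnames(PI)))
  for (s in seq_len(nrow(A)))
    for (p in seq_len(ncol(PI)))
      for (i in seq_len(ncol(A)))
        out[s, p] <- out[s, p] + A[s, i] * PI[colnames(A)[i], p]
  out
}

bruteCpiVariance <- function(A, PI) {
  out <- matrix(0, nrow(A), ncol(PI),
                dimnames = list(rownames(A), colnames(PI)))
  for (s in seq_len(nrow(A)))
    for (p in seq_len(ncol(PI)))
      for (i in seq_len(ncol(A))) {
        pi <- PI[colnames(A)[i], p]
        out[s, p] <- out[s, p] + A[s, i]^2 * pi * (1 - pi)
      }
  out
}

# BPM straight from a phenotype matrix (generic variant label "P1").
makeBpm <- function(phen, ...) {
  phen <- as.matrix(phen)
  colnames(phen) <- scfaPhenotypes()
  if (is.null(rownames(phen)))
    rownames(phen) <- sprintf("g%03d", seq_len(nrow(phen)))
  storage.mode(phen) <- "integer"
  v <- ifelse(phen == 1L, "P1", "")
  dimnames(v) <- dimnames(phen)
  new("BinaryPhenotypeMatrix", phenotypes = phen, variants = v,
      taxonomy = exampleTaxonomy(rownames(phen), ...))
}

# FunctionalRoleMatrix from a named list genome_id -> role vector.
makeFrm <- function(roleSets, catalogueRoles = NULL, ...) {
  if (is.null(catalogueRoles))
    catalogueRoles <- sort(unique(unlist(roleSets)))
  m <- matrix(FALSE, length(roleSets), length(catalogueRoles),
              dimnames = list(names(roleSets), catalogueRoles))
  for (g in names(roleSets)) m[g, intersect(roleSets[[g]],
                                            catalogueRoles)] <- TRUE
  FunctionalRoleMatrix(m, exampleTaxonomy(names(roleSets), ...))
}

# Random DNA helper for mapping tests.
dnaOf <- function(...) Biostrings::DNAStringSet(c(...))

# Mutate exactly k interior positions (away from the ends, so a semi-global
# alignment cannot clip the mismatches away).
mutateExactly <- function(seq, k) {
  chars <- strsplit(seq, "")[[1L]]
  pos <- round(seq(5L, length(chars) - 5L, length.out = k))
  stopifnot(!anyDuplicated(pos))
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  chars[pos] <- swap[chars[pos]]
  paste(chars, collapse = "")
}
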