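## Seeded synthetic-data generators with known ground truth for every
## pipeline input: reference genomes + annotations, 16S sequences and
## trees, ASV abundance tables, WGS taxon and gene-count tables.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic reference collection and community set
#'
#' Bundles every tunable of the generators behind one mandatory seed.
#' Defaults emulate the reference-collection statistics the rule set was
#' built for: producer prevalences per product follow the reference
#' producer fractions (e.g. about 13% butyrate, 29% propionate, 87%
#' acetate producers), 16S surrogates are 250 nt with i.i.d.-substitution
#' divergence placing within-species identity above 97%, within-family
#' above 90% and across-family far below 90% (so the 90% mapping threshold
#' acts at family resolution), and sample compositions are Dirichlet.
#'
#' @param seed mandatory integer seed; all generator randomness derives
#'   from it.
#' @param nFamilies,generaPerFamily,speciesPerGenus,strainsPerSpecies
#'   taxonomy shape (all >= 1).
#' @param prevalence named producer prevalence per product, in `[0, 1]`.
#' @param phenotypeResolution `"family"` (phenotype constant within a
#'   family; exact CPI recovery) or `"strain"` (i.i.d. per-strain draws at
#'   the family prevalence; deliberate phenotype microheterogeneity).
#' @param extraVariantProb probability of adding each further pathway
#'   variant to a producer genome (multi-variant combinations).
#' @param incompleteFraction fraction of non-producer genomes carrying a
#'   partial (one group removed) pathway gene set.
#' @param seqLength 16S surrogate length (nt).
#' @param speciesDivergence,strainDivergence per-site substitution rates
#'   from the family resp. species ancestor.
#' @param nSamples number of community samples.
#' @param dirichletAlpha Dirichlet concentration for compositions.
#' @param copyNumberRange integer range of 16S copy numbers.
#' @param wgsDepth total WGS read count per sample.
#' @param nCoreGenes number of universal single-copy core genes.
#' @return A `fixtureSpec` list (validated).
#' @export
fixtureSpec <- function(seed,
                        nFamilies = 6L, generaPerFamily = 1L,
                        speciesPerGenus = 2L, strainsPerSpecies = 3L,
                        prevalence = c(butyrate = 0.126, propionate = 0.289,
                                       acetate = 0.868, formate = 0.714,
                                       `L-lactate` = 0.633,
                                       `D-lactate` = 0.45),
                        phenotypeResolution = c("family", "strain"),
                        extraVariantProb = 0.2,
                        incompleteFraction = 0.3,
                        seqLength = 250L,
                        speciesDivergence = 0.02,
                        strainDivergence = 0.004,
                        nSamples = 20L,
                        dirichletAlpha = 1,
                        copyNumberRange = c(1L, 7L),
                        wgsDepth = 1e5,
                        nCoreGenes = 20L) {
  if (missing(seed)) stop("a seed is mandatory")
  phenotypeResolution <- match.arg(phenotypeResolution)
  full <- stats::setNames(rep(0, 6), scfaPhenotypes())
  full[names(prevalence)] <- prevalence
  if (any(full < 0 | full > 1)) stop("prevalences must lie in [0, 1]")
  stopifnot(nFamilies >= 1, generaPerFamily >= 1, speciesPerGenus >= 1,
            strainsPerSpecies >= 1, nSamples >= 1, seqLength >= 1,
            nCoreGenes >= 1, copyNumberRange[1L] >= 1)
  spec <- list(seed = as.integer(seed), nFamilies = nFamilies,
               generaPerFamily = generaPerFamily,
               speciesPerGenus = speciesPerGenus,
               strainsPerSpecies = strainsPerSpecies,
               prevalence = full,
               phenotypeResolution = phenotypeResolution,
               extraVariantProb = extraVariantProb,
               incompleteFraction = incompleteFraction,
               seqLength = as.integer(seqLength),
               speciesDivergence = speciesDivergence,
               strainDivergence = strainDivergence,
               nSamples = as.integer(nSamples),
               dirichletAlpha = dirichletAlpha,
               copyNumberRange = as.integer(copyNumberRange),
               wgsDepth = wgsDepth, nCoreGenes = as.integer(nCoreGenes))
  class(spec) <- "fixtureSpec"
  spec
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

mutateDna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Generate a synthetic reference collection
#'
#' Builds genomes whose role sets are constructed by the pathway rules
#' themselves (one alternative sampled per role group), which guarantees
#' that [buildBpm()] recovers the intended variant calls and phenotypes
#' exactly; non-producers optionally carry partial pathways. 16S
#' surrogates are generated by mutating family then species ancestors so
#' that the 90% identity threshold resolves families, and the returned
#' tree mirrors the simulated divergences.
#'
#' @param spec a [fixtureSpec()].
#' @param pathways a [PathwaySet-class] (default rules if omitted).
#' @return List: `frm` ([FunctionalRoleMatrix-class]), `bpm` (the intended
#'   [BinaryPhenotypeMatrix-class] ground truth), `sequences` (named
#'   [Biostrings::DNAStringSet] of 16S surrogates per genome), `tree`
#'   (`phylo` over genome ids).
#' @export
generateReferenceCollection <- function(spec,
                                        pathways = loadPathwayDefinitions()) {
  stopifnot(inherits(spec, "fixtureSpec"))
  withSeed(spec$seed, {
    ## ----- taxonomy ------------------------------------------------------
    rows <- list()
    for (f in seq_len(spec$nFamilies))
      for (g in seq_len(spec$generaPerFamily))
        for (s in seq_len(spec$speciesPerGenus))
          for (st in seq_len(spec$strainsPerSpecies))
            rows[[length(rows) + 1L]] <- c(f, g, s, st)
    idx <- do.call(rbind, rows)
    n <- nrow(idx)
    ids <- sprintf("G%04d", seq_len(n))
    fam <- sprintf("f%02d", idx[, 1L])
    gen <- sprintf("%s_g%02d", fam, idx[, 2L])
    spp <- sprintf("%s_s%02d", gen, idx[, 3L])
    tx <- data.frame(
      phylum = sprintf("phylum%02d", (idx[, 1L] - 1L) %% 2L + 1L),
      class = sprintf("class%02d", (idx[, 1L] - 1L) %% 2L + 1L),
      order = sprintf("order%02d", idx[, 1L]),
      family = fam, genus = gen, species = spp,
      strain = sprintf("%s_t%02d", spp, idx[, 4L]),
      stringsAsFactors = FALSE)
    rownames(tx) <- ids

    ## ----- phenotypes and role sets --------------------------------------
    prods <- scfaPhenotypes()
    defsByProd <- split(pathways@definitions,
                        vapply(pathways@definitions, `[[`, "", "product"))
    famIds <- unique(fam)
    famProducer <- matrix(FALSE, length(famIds), 6L,
                          dimnames = list(famIds, prods))
    for (p in prods)
      famProducer[, p] <- stats::runif(length(famIds)) < spec$prevalence[p]

    allRoles <- pathways@catalogue$role
    roleMat <- matrix(FALSE, n, length(allRoles),
                      dimnames = list(ids, allRoles))
    phen <- matrix(0L, n, 6L, dimnames = list(ids, prods))
    vari <- matrix("", n, 6L, dimnames = list(ids, prods))

    sampleVariantRoles <- function(def) {
      roles <- character()
      sub <- FALSE
      for (gr in def$groups) {
        k <- sample.int(length(gr$alternatives), 1L)
        alt <- gr$alternatives[[k]]
        roles <- c(roles, alt)
        if (!is.null(def$sublabel) &&
            identical(sort(alt), sort(def$sublabel$when_only)))
          sub <- TRUE
      }
      list(roles = unique(roles),
           label = if (sub) def$sublabel$label else def$label)
    }

    for (i in seq_len(n)) {
      for (p in prods) {
        producer <- if (spec$phenotypeResolution == "family")
          famProducer[fam[i], p]
        else stats::runif(1) < spec$prevalence[p]
        defs <- defsByProd[[p]]
        if (is.null(defs)) next
        if (producer) {
          first <- sample.int(length(defs), 1L)
          chosen <- first
          if (length(defs) > 1L)
            for (k in setdiff(seq_along(defs), first))
              if (stats::runif(1) < spec$extraVariantProb)
                chosen <- c(chosen, k)
          labels <- character()
          for (k in chosen) {
            sv <- sampleVariantRoles(defs[[k]])
            roleMat[i, sv$roles] <- TRUE
            labels <- c(labels, sv$label)
          }
          phen[i, p] <- 1L
          vari[i, p] <- paste(sort(unique(labels)), collapse = "+")
        } else if (stats::runif(1) < spec$incompleteFraction) {
          def <- defs[[sample.int(length(defs), 1L)]]
          if (length(def$groups) > 1L) {
            sv <- sampleVariantRoles(def)
            drop <- def$groups[[sample.int(length(def$groups), 1L)]]
            dropRoles <- unique(unlist(drop$alternatives))
            roleMat[i, setdiff(sv$roles, dropRoles)] <- TRUE
          }
        }
      }
    }

    bpm <- new("BinaryPhenotypeMatrix", phenotypes = phen, variants = vari,
               taxonomy = tx)
    frm <- new("FunctionalRoleMatrix", roles = roleMat, taxonomy = tx)

    ## ----- 16S surrogates and tree ---------------------------------------
    famSeq <- stats::setNames(
      vapply(famIds, function(f) randomDna(spec$seqLength), ""), famIds)
    sppIds <- unique(spp)
    sppSeq <- stats::setNames(vapply(sppIds, function(s) {
      f <- fam[match(s, spp)]
      mutateDna(famSeq[[f]], spec$speciesDivergence)
    }, ""), sppIds)
    seqs <- stats::setNames(vapply(seq_len(n), function(i)
      mutateDna(sppSeq[[spp[i]]], spec$strainDivergence), ""), ids)

    newickSpecies <- function(s) {
      members <- ids[spp == s]
      sprintf("(%s)", paste(sprintf("%s:%g", members,
                                    spec$strainDivergence + 1e-6),
                            collapse = ","))
    }
    newickFamily <- function(f) {
      ss <- unique(spp[fam == f])
      inner <- paste(sprintf("%s:%g", vapply(ss, newickSpecies, ""),
                             spec$speciesDivergence), collapse = ",")
      sprintf("(%s):0.3", inner)
    }
    nwk <- sprintf("(%s);", paste(vapply(famIds, newickFamily, ""),
                                  collapse = ","))
    tree <- ape::read.tree(text = nwk)

    list(frm = frm, bpm = bpm,
         sequences = Biostrings::DNAStringSet(seqs), tree = tree)
  })
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  x / rowSums(x)
}

#' Generate a synthetic 16S ASV dataset with known ground truth
#'
#' Draws per-sample genome compositions from a Dirichlet, emits one ASV
#' per genome (optionally mutated), draws integer 16S copy numbers and
#' applies them in the forward direction (observed read fractions are
#' copy-number-inflated, so the pipeline's copy-number correction must
#' undo them), and records the ground-truth CPI (composition-weighted
#' intended phenotype fraction).
#'
#' @param reference output of [generateReferenceCollection()].
#' @param spec the same [fixtureSpec()] (its seed is re-derived so the
#'   dataset is reproducible independently of the collection call).
#' @param alienAbundance cell fraction of an injected alien ASV unrelated
#'   to the reference (default 0); sets per-sample reference coverage to
#'   `1 - alienAbundance` exactly.
#' @param asvMutationRate extra per-site substitution rate applied to ASVs
#'   relative to their source genome (default 0: exact-match ASVs).
#' @param uniformCopies logical; `TRUE` forces all copy numbers to 1.
#' @return List: `abundance` (samples x ASVs observed read fractions),
#'   `sequences` (ASV [Biostrings::DNAStringSet]), `copies` (named copy
#'   numbers), `truth` (samples x phenotypes ground-truth CPI),
#'   `composition` (samples x genomes cell fractions), `asvGenome` (named
#'   map ASV -> source genome, alien `NA`), `tree` (`phylo` over ASV ids).
#' @export
generateAsvDataset <- function(reference, spec, alienAbundance = 0,
                               asvMutationRate = 0, uniformCopies = FALSE) {
  stopifnot(inherits(spec, "fixtureSpec"))
  withSeed(spec$seed + 1000L, {
    ids <- genomeIds(reference$frm)
    n <- length(ids)
    asvIds <- sprintf("ASV%04d", seq_len(n))
    comp <- rdirichlet(spec$nSamples, rep(spec$dirichletAlpha, n))
    dimnames(comp) <- list(sprintf("S%03d", seq_len(spec$nSamples)), ids)

    seqs <- as.character(reference$sequences)[ids]
    if (asvMutationRate > 0)
      seqs <- vapply(seqs, mutateDna, "", rate = asvMutationRate,
                     USE.NAMES = FALSE)
    names(seqs) <- asvIds
    asvGenome <- stats::setNames(ids, asvIds)

    cellFrac <- comp
    if (alienAbundance > 0) {
      alienId <- "ASVALIEN"
      seqs[alienId] <- randomDna(spec$seqLength)
      asvIds <- c(asvIds, alienId)
      asvGenome[alienId] <- NA_character_
      cellFrac <- cbind(comp * (1 - alienAbundance),
                        matrix(alienAbundance, spec$nSamples, 1L,
                               dimnames = list(rownames(comp), alienId)))
    }
    colnames(cellFrac) <- asvIds

    copies <- if (uniformCopies) stats::setNames(rep(1L, length(asvIds)),
                                                 asvIds)
      else stats::setNames(
        sample(seq(spec$copyNumberRange[1L], spec$copyNumberRange[2L]),
               length(asvIds), replace = TRUE), asvIds)

    ## forward copy-number bias: read fraction proportional to cells x copies
    obs <- sweep(cellFrac, 2L, copies, "*")
    obs <- obs / rowSums(obs)

    truth <- comp %*% phenotypeMatrix(reference$bpm)[ids, ]

    tree <- reference$tree
    tree$tip.label <- names(asvGenome)[match(tree$tip.label, asvGenome)]

    list(abundance = obs, sequences = Biostrings::DNAStringSet(seqs),
         copies = copies, truth = truth, composition = cellFrac,
         asvGenome = asvGenome, tree = tree)
  })
}

#' Generate a synthetic WGS dataset with known ground truth
#'
#' Draws community compositions, aggregates them into a species-level
#' taxon abundance table, and draws functional-role read counts from a
#' multinomial over expected gene abundances (composition times role
#' presence, single copy per genome), with a set of universal single-copy
#' core genes present in every genome. Ground-truth per-variant carriage
#' (composition-weighted fraction of cells carrying each pathway variant)
#' is recorded.
#'
#' @inheritParams generateAsvDataset
#' @return List: `taxonAbundance` (samples x species), `taxa` (species
#'   seven-rank paths), `geneCounts` (roles x samples), `coreGenes`
#'   (character), `carriage` (samples x `"product.variant"` ground truth),
#'   `composition` (samples x genomes).
#' @export
generateWgsDataset <- function(reference, spec) {
  stopifnot(inherits(spec, "fixtureSpec"))
  withSeed(spec$seed + 2000L, {
    frm <- reference$frm
    ids <- genomeIds(frm)
    n <- length(ids)
    comp <- rdirichlet(spec$nSamples, rep(spec$dirichletAlpha, n))
    dimnames(comp) <- list(sprintf("W%03d", seq_len(spec$nSamples)), ids)

    tx <- taxonomy(frm)
    species <- unique(tx$species)
    taxAb <- vapply(species, function(s)
      rowSums(comp[, tx$species == s, drop = FALSE]), numeric(spec$nSamples))
    if (spec$nSamples == 1L) taxAb <- matrix(taxAb, 1L,
                                             dimnames = list(rownames(comp),
                                                             species))
    taxa <- tx[match(species, tx$species), , drop = FALSE]
    taxa$strain <- "undefined"
    rownames(taxa) <- species

    coreGenes <- sprintf("core%02d", seq_len(spec$nCoreGenes))
    presence <- t(roleMatrix(frm)) * 1          # roles x genomes
    presence <- rbind(presence,
                      matrix(1, spec$nCoreGenes, n,
                             dimnames = list(coreGenes, ids)))
    expected <- presence %*% t(comp)          # roles x samples
    countsList <- lapply(seq_len(spec$nSamples), function(j) {
      pr <- expected[, j]
      if (sum(pr) == 0) return(integer(nrow(expected)))
      stats::rmultinom(1L, size = spec$wgsDepth, prob = pr / sum(pr))[, 1L]
    })
    geneCounts <- do.call(cbind, countsList)
    dimnames(geneCounts) <- list(rownames(expected), rownames(comp))

    vmat <- variantCalls(reference$bpm)[ids, , drop = FALSE]
    entries <- list()
    for (p in colnames(vmat)) {
      labs <- unique(unlist(strsplit(vmat[nzchar(vmat[, p]), p], "+",
                                     fixed = TRUE)))
      for (lb in sort(labs)) {
        carrier <- vapply(vmat[, p], function(s)
          lb %in% strsplit(s, "+", fixed = TRUE)[[1L]], NA)
        entries[[paste(p, lb, sep = ".")]] <- as.numeric(comp %*% carrier)
      }
    }
    carriage <- do.call(cbind, entries)
    if (!is.null(carriage)) rownames(carriage) <- rownames(comp)

    list(taxonAbundance = taxAb, taxa = taxa, geneCounts = geneCounts,
         coreGenes = coreGenes, carriage = carriage, composition = comp)
  })
}
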