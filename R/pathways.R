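## Pathway-rule engine: declarative variant grammar -> binary phenotypes.

normalizeAlternative <- function(a) {
  a <- as.character(unlist(a))
  if (!length(a) || any(!nzchar(a)))
    stop("empty role in pathway alternative")
  a
}

## A group spec in the config is a single role string, a bare list/vector of
## alternatives, or a map with 'alternatives' plus optional flags.
normalizeGroup <- function(g) {
  required <- TRUE
  relaxable <- FALSE
  if (is.list(g) && !is.null(names(g)) && "alternatives" %in% names(g)) {
    if (!is.null(g$required)) required <- isTRUE(g$required)
    if (!is.null(g$relaxable)) relaxable <- isTRUE(g$relaxable)
    g <- g$alternatives
  }
  alts <- if (is.character(g)) {
    lapply(g, identity)           # each string is one single-role alternative
  } else if (is.list(g)) {
    lapply(g, normalizeAlternative)
  } else {
    stop("cannot parse role group in pathway config")
  }
  if (!length(alts)) stop("role group with no alternatives")
  list(alternatives = alts, required = required, relaxable = relaxable)
}

#' Load pathway-variant definitions
#'
#' Parses the declarative pathway grammar (YAML: product -> variants ->
#' role groups, with named shared segments per product) into a
#' [PathwaySet-class]. The default config encodes the reference rules for
#' butyrate (variants P1 acetyl-CoA, P2 succinate, P3 glutamate, P4 lysine,
#' all using the shared universal crotonyl-CoA/butyryl-CoA segment and a
#' terminal release OR-group), propionate (P1 succinate, P2 lactate,
#' P3 propanediol with the B12-independent sub-label `P3*`), acetate,
#' formate and the two lactate isoforms.
#'
#' @param config path to a YAML rule file; `NULL` uses the packaged default.
#' @param relaxed logical; in relaxed mode, groups flagged `relaxable` in
#'   the config (the propionate P1 CoA-transferase group, for genomes of
#'   known producers lacking both known transferases) are not required.
#' @return A [PathwaySet-class].
#' @export
#' @examples
#' ps <- loadPathwayDefinitions()
#' ps
loadPathwayDefinitions <- function(config = NULL, relaxed = FALSE) {
  if (is.null(config))
    config <- system.file("extdata", "scfa_pathways.yaml",
                          package = "SCFAprofiler", mustWork = TRUE)
  cfg <- yaml::read_yaml(config)
  cat_entries <- cfg$catalogue
  catalogue <- if (length(cat_entries)) {
    data.frame(
      role = vapply(cat_entries, function(x) as.character(x$role), ""),
      ec = vapply(cat_entries, function(x)
        if (is.null(x$ec)) "" else as.character(x$ec), ""),
      description = vapply(cat_entries, function(x)
        if (is.null(x$description)) "" else as.character(x$description), ""),
      stringsAsFactors = FALSE)
  } else {
    data.frame(role = character(), ec = character(),
               description = character())
  }
  if (anyDuplicated(catalogue$role))
    stop("duplicate role_id in catalogue: ",
         catalogue$role[duplicated(catalogue$role)][1L])

  definitions <- list()
  sharedAll <- list()
  for (product in names(cfg$pathways)) {
    pw <- cfg$pathways[[product]]
    shared <- lapply(pw$shared, function(seg) lapply(seg$groups, normalizeGroup))
    sharedAll[[product]] <- shared
    for (label in names(pw$variants)) {
      vr <- pw$variants[[label]]
      groups <- lapply(vr$groups, normalizeGroup)
      for (segname in vr$shared) {
        if (is.null(shared[[segname]]))
          stop(sprintf("variant %s/%s references unknown shared segment '%s'",
                       product, label, segname))
        groups <- c(groups, shared[[segname]])
      }
      sub <- NULL
      if (!is.null(vr$sublabel))
        sub <- list(label = as.character(vr$sublabel$label),
                    when_only = normalizeAlternative(vr$sublabel$when_only))
      definitions[[length(definitions) + 1L]] <-
        list(product = product, label = label, groups = groups, sublabel = sub)
    }
  }
  used <- unique(unlist(lapply(definitions, function(d)
    unlist(lapply(d$groups, `[[`, "alternatives")))))
  bad <- setdiff(used, catalogue$role)
  if (length(bad))
    stop("pathway config references undeclared role(s): ",
         paste(bad, collapse = ", "))

  if (relaxed) {
    definitions <- lapply(definitions, function(d) {
      d$groups <- lapply(d$groups, function(g) {
        if (g$relaxable) g$required <- FALSE
        g
      })
      d
    })
  }
  new("PathwaySet", definitions = definitions, shared = sharedAll,
      catalogue = catalogue, relaxed = relaxed)
}

groupSatisfied <- function(group, present) {
  if (!group$required) return(TRUE)
  for (alt in group$alternatives)
    if (all(alt %in% present)) return(TRUE)
  FALSE
}

variantComplete <- function(def, present) {
  for (g in def$groups) if (!groupSatisfied(g, present)) return(FALSE)
  TRUE
}

## Apply a sub-label rule: report e.g. "P3*" when the named alternative is
## the only satisfied alternative of its group.
resolveLabel <- function(def, present) {
  lab <- def$label
  sub <- def$sublabel
  if (is.null(sub)) return(lab)
  for (g in def$groups) {
    hasTarget <- any(vapply(g$alternatives, function(a)
      identical(sort(a), sort(sub$when_only)), NA))
    if (!hasTarget) next
    sat <- vapply(g$alternatives, function(a) all(a %in% present), NA)
    target <- vapply(g$alternatives, function(a)
      identical(sort(a), sort(sub$when_only)), NA)
    if (any(sat & target) && !any(sat & !target)) lab <- sub$label
  }
  lab
}

#' Call pathway variants for one genome
#'
#' A variant is called complete exactly when every one of its role groups
#' (own plus referenced shared segments) has at least one alternative fully
#' present. Missing roles yield absent calls, never errors; adding roles
#' can only add calls (monotonicity).
#'
#' @param roles character vector of present role ids for one genome.
#' @param pathways a [PathwaySet-class] from [loadPathwayDefinitions()].
#' @return Named list, one element per product, each a character vector of
#'   complete variant labels (sorted; possibly empty).
#' @export
#' @examples
#' ps <- loadPathwayDefinitions()
#' callPathwayVariants(c("Thl", "Hbd", "Crt", "Bcd-EtfAB", "But"), ps)$butyrate
callPathwayVariants <- function(roles, pathways) {
  stopifnot(is(pathways, "PathwaySet"))
  roles <- as.character(roles)
  out <- stats::setNames(
    vector("list", length(pathwayProducts(pathways))),
    pathwayProducts(pathways))
  for (p in names(out)) out[[p]] <- character()
  for (def in pathways@definitions) {
    if (variantComplete(def, roles))
      out[[def$product]] <- c(out[[def$product]], resolveLabel(def, roles))
  }
  lapply(out, function(x) sort(unique(x)))
}

#' Translate variant calls to binary phenotypes
#'
#' A product phenotype is 1 exactly when at least one of its pathway
#' variants is complete.
#'
#' @param calls named list of variant-label vectors from
#'   [callPathwayVariants()].
#' @return Named integer vector over [scfaPhenotypes()], values in `{0, 1}`.
#' @export
assignBinaryPhenotypes <- function(calls) {
  ph <- stats::setNames(integer(length(scfaPhenotypes())), scfaPhenotypes())
  for (p in names(ph))
    ph[p] <- as.integer(length(calls[[p]]) > 0L)
  ph
}

## strip sub-label decorations ("P3*" -> "P3") and deduplicate within a
## rendered combination
collapseSublabels <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    labs <- sort(unique(sub("\\*$", "", strsplit(s, "+", fixed = TRUE)[[1L]])))
    paste(labs, collapse = "+")
  }, "", USE.NAMES = FALSE)
}

#' Build a Binary Phenotype Matrix
#'
#' Runs the rule engine over every genome of a [FunctionalRoleMatrix-class]
#' and assembles the genomes x phenotypes 0/1 matrix together with the
#' canonical sorted variant-combination label per product (e.g. `"P1+P3"`).
#'
#' @param frm a [FunctionalRoleMatrix-class].
#' @param pathways a [PathwaySet-class]; default rules if omitted.
#' @return A [BinaryPhenotypeMatrix-class].
#' @export
#' @examples
#' m <- matrix(TRUE, 1, 2, dimnames = list("g1", c("Pta", "AckA")))
#' bpm <- buildBpm(FunctionalRoleMatrix(m, exampleTaxonomy("g1")))
#' phenotypeMatrix(bpm)
buildBpm <- function(frm, pathways = loadPathwayDefinitions()) {
  stopifnot(is(frm, "FunctionalRoleMatrix"))
  ids <- genomeIds(frm)
  if (!length(ids)) stop("empty genome collection")
  phen <- matrix(0L, length(ids), 6L,
                 dimnames = list(ids, scfaPhenotypes()))
  vari <- matrix("", length(ids), 6L,
                 dimnames = list(ids, scfaPhenotypes()))
  rm_ <- roleMatrix(frm)
  for (i in seq_along(ids)) {
    present <- colnames(rm_)[rm_[i, ]]
    calls <- callPathwayVariants(present, pathways)
    for (p in scfaPhenotypes()) {
      v <- calls[[p]]
      if (length(v)) {
        phen[i, p] <- 1L
        vari[i, p] <- paste(v, collapse = "+")
      }
    }
  }
  new("BinaryPhenotypeMatrix", phenotypes = phen, variants = vari,
      taxonomy = taxonomy(frm))
}

#' Summarize the distribution of pathway-variant combinations
#'
#' For each product, partitions producer genomes by their exact variant
#' combination and appends a `"Total"` row counting genomes with at least
#' one complete variant. Species are counted as distinct taxonomically
#' defined species names among those genomes; genomes with species
#' `"undefined"` contribute to genome counts but not species counts.
#'
#' @param bpm a [BinaryPhenotypeMatrix-class].
#' @param products products to summarize (default all six).
#' @param collapseSub collapse sub-labels (`"P3*"` to `"P3"`) before
#'   grouping, as in producer-distribution summaries.
#' @return data.frame with columns `product`, `combination`, `n_genomes`,
#'   `n_species`; combination `"Total"` closes each product block.
#' @export
summarizeVariantDistribution <- function(bpm, products = scfaPhenotypes(),
                                         collapseSub = TRUE) {
  stopifnot(is(bpm, "BinaryPhenotypeMatrix"))
  v <- variantCalls(bpm, collapseSub = collapseSub)
  species <- taxonomy(bpm)$species
  out <- list()
  for (p in products) {
    combos <- v[, p]
    producer <- nzchar(combos)
    if (!any(producer)) {
      out[[p]] <- data.frame(product = p, combination = "Total",
                             n_genomes = 0L, n_species = 0L,
                             stringsAsFactors = FALSE)
      next
    }
    sp <- species[producer]
    cb <- combos[producer]
    nsp <- function(s) length(unique(s[s != "undefined"]))
    tab <- vapply(split(seq_along(cb), cb), length, 0L)
    spc <- vapply(split(sp, cb), nsp, 0L)
    ord <- order(names(tab))
    rows <- data.frame(product = p, combination = names(tab)[ord],
                       n_genomes = unname(tab[ord]),
                       n_species = unname(spc[ord]),
                       stringsAsFactors = FALSE)
    rows <- rbind(rows, data.frame(
      product = p, combination = "Total",
      n_genomes = sum(producer), n_species = nsp(sp),
      stringsAsFactors = FALSE))
    out[[p]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Minimal role set completing a pathway variant
#'
#' Returns a role set that makes the named variant (and only the roles it
#' needs) complete, picking one alternative per group. Used by the
#' synthetic-data generators to construct genomes by rule, which guarantees
#' the rule engine recovers the intended calls.
#'
#' @param pathways a [PathwaySet-class].
#' @param product product name.
#' @param label variant label within the product.
#' @param pick integer or function: which alternative to take from each
#'   group. An integer `k` takes alternative `min(k, n_alts)`; a function
#'   receives the number of alternatives and returns an index (e.g. for
#'   randomized picks).
#' @return Character vector of role ids.
#' @export
#' @examples
#' ps <- loadPathwayDefinitions()
#' rolesForVariant(ps, "butyrate", "P1")
rolesForVariant <- function(pathways, product, label, pick = 1L) {
  stopifnot(is(pathways, "PathwaySet"))
  for (def in pathways@definitions) {
    if (def$product == product && def$label == label) {
      roles <- character()
      for (g in def$groups) {
        k <- if (is.function(pick)) pick(length(g$alternatives))
             else min(as.integer(pick), length(g$alternatives))
        roles <- c(roles, g$alternatives[[k]])
      }
      return(unique(roles))
    }
  }
  stop(sprintf("no variant '%s' defined for product '%s'", label, product))
}

#' Seven-rank placeholder taxonomy
#'
#' Convenience constructor of a minimal valid taxonomy table (every rank
#' `"undefined"` unless supplied), mainly for examples and tests.
#'
#' @param genome_ids character vector of genome ids.
#' @param ... named rank overrides, each a scalar or vector recycled over
#'   genomes (e.g. `species = c("s1", "s2")`).
#' @return data.frame with the seven rank columns, rownames `genome_ids`.
#' @export
exampleTaxonomy <- function(genome_ids, ...) {
  tx <- as.data.frame(
    stats::setNames(rep(list(rep("undefined", length(genome_ids))),
                        length(taxonomyRanks())),
                    taxonomyRanks()),
    check.names = FALSE)
  over <- list(...)
  for (nm in names(over)) {
    stopifnot(nm %in% taxonomyRanks())
    tx[[nm]] <- rep_len(over[[nm]], length(genome_ids))
  }
  rownames(tx) <- genome_ids
  tx
}
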