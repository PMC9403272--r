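#' @import methods
NULL

#' Fermentation products tracked by the phenotype model
#'
#' The six fermentation end products for which binary production phenotypes
#' are called: butyrate, propionate, acetate, formate, L-lactate, D-lactate.
#'
#' @return Character vector of length six, in canonical column order.
#' @export
#' @examples
#' scfaPhenotypes()
scfaPhenotypes <- function() {
  c("butyrate", "propionate", "acetate", "formate", "L-lactate", "D-lactate")
}

#' Taxonomic ranks used throughout the package
#'
#' Seven-rank taxonomy paths (phylum down to strain). Ranks without a
#' defined name carry the sentinel label `"undefined"`.
#'
#' @return Character vector of the seven rank names, highest first.
#' @export
taxonomyRanks <- function() {
  c("phylum", "class", "order", "family", "genus", "species", "strain")
}

## ---------------------------------------------------------------------------
## FunctionalRoleMatrix
## ---------------------------------------------------------------------------

#' FunctionalRoleMatrix: genomes x functional roles
#'
#' Binary presence/absence of functional roles (enzymes) across reference
#' genomes, together with a seven-rank taxonomy per genome. This is the
#' input to the pathway-rule engine; how the annotations were produced
#' (homology search, manual curation) is upstream of this package.
#'
#' @slot roles logical matrix, genomes in rows (rownames are genome ids),
#'   functional roles in columns.
#' @slot taxonomy data.frame with the seven columns of [taxonomyRanks()],
#'   one row per genome, rownames matching `roles`.
#' @export
setClass("FunctionalRoleMatrix",
  representation(roles = "matrix", taxonomy = "data.frame"))

setValidity("FunctionalRoleMatrix", function(object) {
  r <- object@roles
  if (!is.logical(r)) return("'roles' must be a logical matrix")
  if (is.null(rownames(r)) || anyDuplicated(rownames(r)))
    return("genome ids (rownames of 'roles') must be unique and non-missing")
  if (is.null(colnames(r)) || anyDuplicated(colnames(r)))
    return("role ids (colnames of 'roles') must be unique and non-missing")
  if (any(!nzchar(rownames(r)))) return("empty genome id")
  tx <- object@taxonomy
  if (!identical(colnames(tx), taxonomyRanks()))
    return("taxonomy must have exactly the seven rank columns")
  if (!identical(rownames(tx), rownames(r)))
    return("taxonomy rows must match genome ids")
  TRUE
})

#' Construct a FunctionalRoleMatrix
#'
#' @param roles logical or 0/1 numeric matrix, genomes x roles, with
#'   dimnames.
#' @param taxonomy data.frame of seven-rank taxonomy labels, one row per
#'   genome in the same order as `roles` (or with matching rownames).
#' @return A [FunctionalRoleMatrix-class] object.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("Pta", "AckA")))
#' tx <- exampleTaxonomy(c("g1", "g2"))
#' FunctionalRoleMatrix(m, tx)
FunctionalRoleMatrix <- function(roles, taxonomy) {
  if (anyDuplicated(rownames(roles)))
    stop("duplicate genome_id: ",
         rownames(roles)[duplicated(rownames(roles))][1L])
  if (is.numeric(roles)) {
    stopifnot(all(roles %in% c(0, 1)))
    storage.mode(roles) <- "logical"
  }
  taxonomy <- as.data.frame(taxonomy)
  if (!is.null(rownames(taxonomy)) &&
      !identical(rownames(taxonomy), rownames(roles)) &&
      all(rownames(roles) %in% rownames(taxonomy))) {
    taxonomy <- taxonomy[rownames(roles), , drop = FALSE]
  }
  rownames(taxonomy) <- rownames(roles)
  new("FunctionalRoleMatrix", roles = roles, taxonomy = taxonomy)
}

## ---------------------------------------------------------------------------
## PathwaySet
## ---------------------------------------------------------------------------

#' PathwaySet: the declarative pathway-rule set
#'
#' A collection of pathway-variant definitions. Each definition is an AND
#' over role groups; each group is an OR over alternatives (non-orthologous
#' gene displacements); an alternative is one role or a co-required role
#' combination. Shared segments (e.g. the universal crotonyl-CoA to
#' butyryl-CoA step of all butyrate routes) are stored once per product and
#' referenced by variants.
#'
#' @slot definitions list of variant definitions (product, label, groups,
#'   optional sublabel rule); groups carry `alternatives` (list of character
#'   vectors) and `required` flags.
#' @slot shared named list (per product) of shared segment group lists.
#' @slot catalogue data.frame of the role catalogue (role, ec, description).
#' @slot relaxed logical; if `TRUE`, groups flagged relaxable in the config
#'   are not required (see [loadPathwayDefinitions()]).
#' @export
setClass("PathwaySet",
  representation(definitions = "list", shared = "list",
                 catalogue = "data.frame", relaxed = "logical"))

setValidity("PathwaySet", function(object) {
  defs <- object@definitions
  if (length(defs)) {
    key <- vapply(defs, function(d) paste(d$product, d$label), "")
    if (anyDuplicated(key))
      return(sprintf("duplicate variant label within a product: %s",
                     key[duplicated(key)][1L]))
    roles <- unique(unlist(lapply(defs, function(d)
      unlist(lapply(d$groups, `[[`, "alternatives")))))
    bad <- setdiff(roles, object@catalogue$role)
    if (length(bad))
      return(sprintf("role(s) not in catalogue: %s",
                     paste(bad, collapse = ", ")))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## BinaryPhenotypeMatrix
## ---------------------------------------------------------------------------

#' BinaryPhenotypeMatrix (BPM)
#'
#' Genomes x six fermentation-product phenotypes, each strictly 0/1 (1 =
#' predicted producer), together with the per-genome pathway-variant
#' combination that supports each call (e.g. `"P1+P3"`) and the genome
#' taxonomy. Invariant: a phenotype is 1 exactly when the variant set for
#' that product is non-empty.
#'
#' @slot phenotypes integer matrix genomes x 6 with values in `{0, 1}`;
#'   columns are [scfaPhenotypes()].
#' @slot variants character matrix genomes x 6; sorted `"+"`-joined variant
#'   labels per product, `""` when no variant is complete.
#' @slot taxonomy data.frame of seven-rank taxonomy labels per genome.
#' @export
setClass("BinaryPhenotypeMatrix",
  representation(phenotypes = "matrix", variants = "matrix",
                 taxonomy = "data.frame"))

setValidity("BinaryPhenotypeMatrix", function(object) {
  ph <- object@phenotypes
  if (!identical(colnames(ph), scfaPhenotypes()))
    return("phenotype columns must be the six canonical products")
  if (is.null(rownames(ph)) || anyDuplicated(rownames(ph)))
    return("genome ids must be unique")
  if (!all(ph %in% c(0L, 1L))) return("phenotype values must be 0/1")
  v <- object@variants
  if (!identical(dimnames(v), dimnames(ph)))
    return("variants matrix must mirror the phenotype matrix dimnames")
  if (!all((ph == 1L) == nzchar(v)))
    return("phenotype must be 1 iff the variant set is non-empty")
  if (!identical(colnames(object@taxonomy), taxonomyRanks()))
    return("taxonomy must have exactly the seven rank columns")
  if (!identical(rownames(object@taxonomy), rownames(ph)))
    return("taxonomy rows must match genome ids")
  TRUE
})

## ---------------------------------------------------------------------------
## AsvMapping
## ---------------------------------------------------------------------------

#' AsvMapping: ASV to reference-genome sequence mapping
#'
#' All reference hits at or above the identity threshold for each ASV.
#' An ASV is mapped when it has at least one retained hit.
#'
#' @slot hits data.frame with columns `asv_id`, `genome_id`, `identity`
#'   (percent, in `[0, 100]`), one row per retained hit.
#' @slot asvIds character vector of all query ASV ids (mapped or not).
#' @slot threshold numeric percent-identity threshold used.
#' @export
setClass("AsvMapping",
  representation(hits = "data.frame", asvIds = "character",
                 threshold = "numeric"))

setValidity("AsvMapping", function(object) {
  h <- object@hits
  if (!all(c("asv_id", "genome_id", "identity") %in% colnames(h)))
    return("hits must have asv_id, genome_id, identity columns")
  if (nrow(h) && (any(h$identity < 0) || any(h$identity > 100)))
    return("identities must lie in [0, 100]")
  if (nrow(h) && !all(h$asv_id %in% object@asvIds))
    return("hit asv_id absent from asvIds")
  if (nrow(h) && any(h$identity < object@threshold))
    return("hits below the identity threshold must not be retained")
  TRUE
})

## ---------------------------------------------------------------------------
## CpiProfile
## ---------------------------------------------------------------------------

#' CpiProfile: Community Phenotype Indices with prediction errors
#'
#' Per sample and phenotype: CPI (abundance-weighted mean Phenotype Index,
#' the expected fraction of community cells with the capability), the
#' prediction variance `v = sum_i A_i^2 PI_i (1 - PI_i)`, its square root
#' `sigma` (the default error scale), the per-sample reference coverage,
#' and whether the sample passed the coverage filter.
#'
#' @slot cpi numeric matrix samples x phenotypes, values in `[0, 1]`.
#' @slot sigma numeric matrix, `sqrt(variance)`.
#' @slot variance numeric matrix, the printed-formula sum.
#' @slot coverage named numeric vector per sample, in `[0, 1]`.
#' @slot retained named logical vector per sample.
#' @export
setClass("CpiProfile",
  representation(cpi = "matrix", sigma = "matrix", variance = "matrix",
                 coverage = "numeric", retained = "logical"))

setValidity("CpiProfile", function(object) {
  if (!identical(dim(object@cpi), dim(object@sigma)) ||
      !identical(dim(object@cpi), dim(object@variance)))
    return("cpi, sigma and variance must have identical dimensions")
  if (any(object@cpi < -1e-9 | object@cpi > 1 + 1e-9, na.rm = TRUE))
    return("CPI values must lie in [0, 1]")
  if (length(object@coverage) != nrow(object@cpi) ||
      length(object@retained) != nrow(object@cpi))
    return("coverage/retained must have one entry per sample")
  TRUE
})
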