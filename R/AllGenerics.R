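#' Accessor generics
#'
#' Standard accessors for the package's S4 containers. Use these rather
#' than `@` slot access.
#'
#' @param x an object of one of the package classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname accessors
#' @export
setGeneric("roleMatrix", function(x) standardGeneric("roleMatrix"))

#' @rdname accessors
#' @export
setGeneric("phenotypeMatrix", function(x) standardGeneric("phenotypeMatrix"))

#' @rdname accessors
#' @export
setGeneric("variantCalls", function(x, ...) standardGeneric("variantCalls"))

#' @rdname accessors
#' @export
setGeneric("pathwayProducts", function(x) standardGeneric("pathwayProducts"))

#' @rdname accessors
#' @export
setGeneric("mappingHits", function(x) standardGeneric("mappingHits"))

#' @rdname accessors
#' @export
setGeneric("mappedAsvs", function(x) standardGeneric("mappedAsvs"))

#' @rdname accessors
#' @export
setGeneric("unmappedAsvs", function(x) standardGeneric("unmappedAsvs"))

#' @rdname accessors
#' @export
setGeneric("cpi", function(x) standardGeneric("cpi"))

#' @rdname accessors
#' @export
setGeneric("cpiError", function(x) standardGeneric("cpiError"))

#' @rdname accessors
#' @export
setGeneric("cpiVariance", function(x) standardGeneric("cpiVariance"))

#' @rdname accessors
#' @export
setGeneric("sampleCoverage", function(x) standardGeneric("sampleCoverage"))

#' @rdname accessors
#' @export
setGeneric("isRetained", function(x) standardGeneric("isRetained"))

## FunctionalRoleMatrix ------------------------------------------------------

#' @rdname accessors
setMethod("genomeIds", "FunctionalRoleMatrix",
          function(x) rownames(x@roles))

#' @rdname accessors
setMethod("taxonomy", "FunctionalRoleMatrix", function(x) x@taxonomy)

#' @rdname accessors
setMethod("roleMatrix", "FunctionalRoleMatrix", function(x) x@roles)

setMethod("show", "FunctionalRoleMatrix", function(object) {
  cat(sprintf("FunctionalRoleMatrix: %d genomes x %d functional roles\n",
              nrow(object@roles), ncol(object@roles)))
  cat(sprintf("  roles present: %d of %d cells\n",
              sum(object@roles), length(object@roles)))
})

## PathwaySet ----------------------------------------------------------------

#' @rdname accessors
setMethod("pathwayProducts", "PathwaySet", function(x)
  unique(vapply(x@definitions, `[[`, "", "product")))

setMethod("length", "PathwaySet", function(x) length(x@definitions))

setMethod("show", "PathwaySet", function(object) {
  prods <- vapply(object@definitions, `[[`, "", "product")
  cat(sprintf("PathwaySet: %d variant definitions across %d products%s\n",
              length(object@definitions), length(unique(prods)),
              if (object@relaxed) " (relaxed mode)" else ""))
  for (p in unique(prods)) {
    labs <- vapply(object@definitions[prods == p], `[[`, "", "label")
    cat(sprintf("  %-11s %s\n", p, paste(labs, collapse = ", ")))
  }
})

## BinaryPhenotypeMatrix -----------------------------------------------------

#' @rdname accessors
setMethod("genomeIds", "BinaryPhenotypeMatrix",
          function(x) rownames(x@phenotypes))

#' @rdname accessors
setMethod("taxonomy", "BinaryPhenotypeMatrix", function(x) x@taxonomy)

#' @rdname accessors
setMethod("phenotypeMatrix", "BinaryPhenotypeMatrix",
          function(x) x@phenotypes)

#' @param collapseSub logical; collapse sub-labelled variants (e.g.
#'   `"P3*"`) onto their parent label (`"P3"`), as in producer summaries.
#' @param ... passed between methods.
#' @rdname accessors
setMethod("variantCalls", "BinaryPhenotypeMatrix",
  function(x, collapseSub = FALSE, ...) {
    v <- x@variants
    if (collapseSub) v[] <- collapseSublabels(v)
    v
  })

setMethod("show", "BinaryPhenotypeMatrix", function(object) {
  ph <- object@phenotypes
  cat(sprintf("BinaryPhenotypeMatrix: %d genomes x %d phenotypes\n",
              nrow(ph), ncol(ph)))
  cat("  producers:",
      paste(sprintf("%s %d", colnames(ph), colSums(ph)), collapse = ", "),
      "\n")
})

## AsvMapping ----------------------------------------------------------------

#' @rdname accessors
setMethod("mappingHits", "AsvMapping", function(x) x@hits)

#' @rdname accessors
setMethod("mappedAsvs", "AsvMapping",
          function(x) intersect(x@asvIds, unique(x@hits$asv_id)))

#' @rdname accessors
setMethod("unmappedAsvs", "AsvMapping",
          function(x) setdiff(x@asvIds, x@hits$asv_id))

setMethod("show", "AsvMapping", function(object) {
  cat(sprintf(
    "AsvMapping: %d of %d ASVs mapped at >= %.6g%% identity (%d hits)\n",
    length(mappedAsvs(object)), length(object@asvIds), object@threshold,
    nrow(object@hits)))
})

## CpiProfile ----------------------------------------------------------------

#' @rdname accessors
setMethod("cpi", "CpiProfile", function(x) x@cpi)

#' @rdname accessors
setMethod("cpiError", "CpiProfile", function(x) x@sigma)

#' @rdname accessors
setMethod("cpiVariance", "CpiProfile", function(x) x@variance)

#' @rdname accessors
setMethod("sampleCoverage", "CpiProfile", function(x) x@coverage)

#' @rdname accessors
setMethod("isRetained", "CpiProfile", function(x) x@retained)

setMethod("show", "CpiProfile", function(object) {
  cat(sprintf("CpiProfile: %d samples x %d phenotypes (%d retained)\n",
              nrow(object@cpi), ncol(object@cpi), sum(object@retained)))
  if (nrow(object@cpi)) {
    m <- colMeans(object@cpi[object@retained, , drop = FALSE])
    cat("  mean CPI:",
        paste(sprintf("%s %.3f", colnames(object@cpi), m), collapse = ", "),
        "\n")
  }
})
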