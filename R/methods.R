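# Accessors and show() methods.

#' @rdname SunCatalog-class
#' @export
setMethod("sunRecords", "SunCatalog", function(x) x@records)

#' @rdname SunCatalog-class
#' @export
setMethod("sunRegion", "SunCatalog", function(x) x@sunRegion)

#' @rdname SunCatalog-class
#' @export
setMethod("parentName", "SunCatalog", function(x) x@parentName)

#' @rdname SunCatalog-class
#' @export
setMethod("paralogNames", "SunCatalog", function(x) x@paralogNames)

#' @rdname SunCatalog-class
#' @export
setMethod("length", "SunCatalog", function(x) length(x@records))

#' @rdname SunCatalog-class
#' @export
setMethod("show", "SunCatalog", function(object) {
  cat(sprintf("SunCatalog with %d SUN record(s)\n", length(object)))
  cat(sprintf("  parent: %s; paralogs: %s\n", object@parentName,
              paste(object@paralogNames, collapse = ", ")))
  cat(sprintf("  SUN region: %s-%s\n",
              format(object@sunRegion[1], scientific = FALSE),
              format(object@sunRegion[2], scientific = FALSE)))
  if (length(object)) {
    tab <- table(mcols(object@records)$paralog)
    cat("  per paralog:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
})

#' @rdname DepthTrack-class
#' @export
setMethod("depthValues", "DepthTrack", function(x) x@depth)

#' @rdname DepthTrack-class
#' @export
setMethod("trackPositions", "DepthTrack", function(x) {
  seq.int(x@start, length.out = length(x@depth))
})

#' @rdname DepthTrack-class
#' @export
setMethod("length", "DepthTrack", function(x) length(x@depth))

#' @rdname DepthTrack-class
#' @export
setMethod("show", "DepthTrack", function(object) {
  cat(sprintf("DepthTrack %s:%s-%s (%d positions, mean depth %.2f)\n",
              object@chrom,
              format(object@start, scientific = FALSE),
              format(object@start + length(object@depth) - 1L,
                     scientific = FALSE),
              length(object@depth), mean(object@depth)))
})

#' @rdname TotalAlleleEstimate-class
#' @param object A `TotalAlleleEstimate`.
#' @export
setMethod("show", "TotalAlleleEstimate", function(object) {
  cat(sprintf(
    "TotalAlleleEstimate: ratio %.3f -> %.2f alleles (rounded: %d)\n",
    object@ratio, object@totalReal, object@totalInt))
})

#' @rdname AlleleCountEstimate-class
#' @export
setMethod("alleleCounts", "AlleleCountEstimate", function(x) x@counts)

#' @rdname AlleleCountEstimate-class
#' @export
setMethod("totalAlleles", "AlleleCountEstimate", function(x) x@totalInt)

#' @rdname AlleleCountEstimate-class
#' @export
setMethod("estimateFlags", "AlleleCountEstimate", function(x) x@flags)

#' @rdname AlleleCountEstimate-class
#' @export
setMethod("show", "AlleleCountEstimate", function(object) {
  cat(sprintf("AlleleCountEstimate (total %d):\n", object@totalInt))
  cat(" ", paste(sprintf("%s=%d", names(object@counts), object@counts),
                 collapse = " "), "\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

#' @rdname GenomeConfig-class
#' @export
setMethod("locusAlleles", "GenomeConfig", function(x) x@locusAlleles)

#' @rdname GenomeConfig-class
#' @export
setMethod("totalAlleles", "GenomeConfig", function(x) {
  as.integer(sum(x@locusAlleles))
})

#' @rdname GenomeConfig-class
#' @export
setMethod("show", "GenomeConfig", function(object) {
  cat(sprintf("GenomeConfig (%d alleles, %.0fx, seed %d):\n",
              sum(object@locusAlleles), object@baseDepth, object@seed))
  cat(" ", paste(sprintf("%s=%d", names(object@locusAlleles),
                         object@locusAlleles), collapse = " "), "\n")
  if (nrow(object@conversionTracts))
    cat(sprintf("  %d conversion tract(s)\n", nrow(object@conversionTracts)))
  pv <- object@pointVariants
  if (nrow(pv) && any(pv$nAlleles > 0)) {
    pv <- pv[pv$nAlleles > 0, ]
    cat("  variants:",
        paste(sprintf("%s(%d)", pv$name, pv$nAlleles), collapse = " "), "\n")
  }
})

#' @rdname ParalogPositionGroup-class
#' @param object A `ParalogPositionGroup`.
#' @export
setMethod("show", "ParalogPositionGroup", function(object) {
  cat(sprintf("ParalogPositionGroup '%s' (%d members, variant on %s)\n",
              object@name, nrow(object@members), object@variantLocus))
})
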