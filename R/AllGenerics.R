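#' @rdname SunCatalog-class
#' @param x,object A `SunCatalog`.
#' @export
setGeneric("sunRecords", function(x) standardGeneric("sunRecords"))

#' @rdname SunCatalog-class
#' @export
setGeneric("sunRegion", function(x) standardGeneric("sunRegion"))

#' @rdname SunCatalog-class
#' @export
setGeneric("parentName", function(x) standardGeneric("parentName"))

#' @rdname SunCatalog-class
#' @export
setGeneric("paralogNames", function(x) standardGeneric("paralogNames"))

#' @rdname DepthTrack-class
#' @param x,object A `DepthTrack`.
#' @export
setGeneric("depthValues", function(x) standardGeneric("depthValues"))

#' @rdname DepthTrack-class
#' @export
setGeneric("trackPositions", function(x) standardGeneric("trackPositions"))

#' @rdname AlleleCountEstimate-class
#' @param x,object An `AlleleCountEstimate`.
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))

#' @rdname AlleleCountEstimate-class
#' @export
setGeneric("totalAlleles", function(x) standardGeneric("totalAlleles"))

#' @rdname AlleleCountEstimate-class
#' @export
setGeneric("estimateFlags", function(x) standardGeneric("estimateFlags"))

#' @rdname GenomeConfig-class
#' @param x,object A `GenomeConfig`.
#' @export
setGeneric("locusAlleles", function(x) standardGeneric("locusAlleles"))
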