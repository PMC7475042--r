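# Combined allele count from the depth ratio between the multicopy and
# single-copy regions on the masked reference. All family reads pile onto
# the parent locus there, so multicopy depth is proportional to the total
# number of family alleles while single-copy depth represents exactly two.

#' Construct a RegionSet
#'
#' @param intervals Two-column matrix or data.frame of 1-based inclusive
#'   (start, end) analysis intervals, or a length-2 vector for a single
#'   interval.
#' @param excluded Optional repeat intervals to mask, same formats.
#' @return A [RegionSet-class].
#' @examples
#' regionSet(c(100, 200), excluded = c(150, 160))
#' @export
regionSet <- function(intervals, excluded = NULL) {
  asMat <- function(x) {
    if (is.null(x)) return(matrix(numeric(0), ncol = 2))
    if (is.null(dim(x))) x <- matrix(x, ncol = 2, byrow = TRUE)
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  }
  new("RegionSet", intervals = asMat(intervals), excluded = asMat(excluded))
}

#' Mean depth over a region set
#'
#' Arithmetic mean of per-position depth over the in-region positions,
#' after subtracting the excluded (repeat-masked) intervals.
#'
#' @param track A [DepthTrack-class].
#' @param regions A [RegionSet-class] (or anything [regionSet()]
#'   accepts).
#' @return Mean depth (reads).
#' @export
meanDepth <- function(track, regions) {
  stopifnot(is(track, "DepthTrack"))
  if (!is(regions, "RegionSet")) regions <- regionSet(regions)
  pos <- intervalPositions(regions@intervals)
  if (nrow(regions@excluded))
    pos <- pos[!pos %in% intervalPositions(regions@excluded)]
  lo <- track@start
  hi <- track@start + length(track@depth) - 1L
  pos <- pos[pos >= lo & pos <= hi]
  if (!length(pos)) stop("empty region after masking")
  mean(track@depth[pos - lo + 1L])
}

#' Combined allele count from the multicopy/single-copy depth ratio
#'
#' The single-copy region represents two alleles, so the combined family
#' allele count is `2 * multiMean / singleMean`. The integer estimate
#' rounds halves away from zero.
#'
#' @param multiMean Mean depth over the multicopy region (reads).
#' @param singleMean Mean depth over the single-copy region (reads).
#' @return A [TotalAlleleEstimate-class].
#' @examples
#' totalAlleleCount(150, 30)  # ratio 5 -> 10 alleles
#' @export
totalAlleleCount <- function(multiMean, singleMean) {
  if (!is.finite(singleMean) || singleMean <= 0)
    stop("uninformative single-copy coverage")
  ratio <- multiMean / singleMean
  totalReal <- 2 * ratio
  new("TotalAlleleEstimate", ratio = ratio, totalReal = totalReal,
      totalInt = as.integer(roundHalfAway(totalReal)))
}
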