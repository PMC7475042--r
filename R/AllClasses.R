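#' SunCatalog: paralog-identifying variant positions in parent coordinates
#'
#' Holds the set of singly unique nucleotides (SUNs) of a paralog family,
#' projected onto parent-locus coordinates, as a [GenomicRanges::GRanges]
#' with metadata columns `paralog`, `parentBase`, `sunBase` and `kind`
#' (`SNV`, `insertion` or `deletion`), plus the paralog set and the SUN
#' region the records are restricted to.
#'
#' @slot records A `GRanges`, one width-1 range per SUN at its parent
#'   position (a deletion is anchored at its first deleted parent base, an
#'   insertion at the preceding parent base).
#' @slot parentName Name of the parent locus.
#' @slot paralogNames Names of the non-parent paralogs.
#' @slot sunRegion Length-2 integer vector, 1-based inclusive bounds of the
#'   region SUNs are restricted to.
#' @export
setClass("SunCatalog", representation(
  records = "GRanges",
  parentName = "character",
  paralogNames = "character",
  sunRegion = "integer"
))

setValidity("SunCatalog", function(object) {
  rec <- object@records
  msg <- character(0)
  m <- mcols(rec)
  need <- c("paralog", "parentBase", "sunBase", "kind")
  if (!all(need %in% colnames(m)))
    return(paste("records must carry metadata columns:",
                 paste(need, collapse = ", ")))
  if (length(rec)) {
    if (!all(m$kind %in% c("SNV", "insertion", "deletion")))
      msg <- c(msg, "kind must be SNV, insertion or deletion")
    if (any(m$parentBase == m$sunBase))
      msg <- c(msg, "parentBase must differ from sunBase")
    if (is.unsorted(start(rec)))
      msg <- c(msg, "records must be sorted by position")
    key <- paste(start(rec), m$sunBase, m$kind, m$parentBase)
    if (anyDuplicated(key))
      msg <- c(msg, "a (position, sun base) pair may belong to only one paralog")
    if (any(start(rec) < object@sunRegion[1] | start(rec) > object@sunRegion[2]))
      msg <- c(msg, "all records must lie within the SUN region")
    if (!all(m$paralog %in% object@paralogNames))
      msg <- c(msg, "record paralogs must be in paralogNames")
  }
  if (length(object@sunRegion) != 2 || object@sunRegion[1] > object@sunRegion[2])
    msg <- c(msg, "sunRegion must be a valid start <= end pair")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' DepthTrack: per-position sequencing depth over a genomic interval
#'
#' @slot chrom Chromosome name.
#' @slot start 1-based position of the first depth value.
#' @slot depth Integer vector of per-position read counts.
#' @export
setClass("DepthTrack", representation(
  chrom = "character",
  start = "integer",
  depth = "integer"
))

setValidity("DepthTrack", function(object) {
  if (length(object@depth) < 1) return("depth track must have >= 1 position")
  if (any(object@depth < 0)) return("depths must be >= 0")
  TRUE
})

#' RegionSet: analysis intervals with a repeat mask
#'
#' A set of 1-based inclusive intervals over which depth is averaged,
#' minus excluded (repeat) intervals which are subtracted before any mean.
#'
#' @slot intervals Two-column matrix (start, end) of analysis intervals.
#' @slot excluded Two-column matrix (start, end) of masked intervals
#'   (zero rows for no mask).
#' @export
setClass("RegionSet", representation(
  intervals = "matrix",
  excluded = "matrix"
))

setValidity("RegionSet", function(object) {
  chk <- function(m, what) {
    if (ncol(m) != 2) return(sprintf("%s must have two columns", what))
    if (nrow(m) && any(m[, 1] > m[, 2]))
      return(sprintf("%s must satisfy start <= end", what))
    TRUE
  }
  v <- chk(object@intervals, "intervals")
  if (!isTRUE(v)) return(v)
  chk(object@excluded, "excluded")
})

#' TotalAlleleEstimate: combined family allele count from depth ratio
#'
#' @slot ratio Multicopy mean depth divided by single-copy mean depth.
#' @slot totalReal `2 * ratio` (the single-copy region represents two
#'   alleles).
#' @slot totalInt `totalReal` rounded to the nearest integer, halves away
#'   from zero.
#' @export
setClass("TotalAlleleEstimate", representation(
  ratio = "numeric",
  totalReal = "numeric",
  totalInt = "integer"
))

#' AlleleCountEstimate: per-locus integer allele counts for one individual
#'
#' @slot counts Named integer vector over the five family loci.
#' @slot totalInt Combined allele count the per-locus counts were fitted
#'   to.
#' @slot flags Character vector of applied corrections/caveats.
#' @export
setClass("AlleleCountEstimate", representation(
  counts = "integer",
  totalInt = "integer",
  flags = "character"
))

setValidity("AlleleCountEstimate", function(object) {
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (is.null(names(object@counts))) return("counts must be named")
  conserved <- sum(object@counts) == object@totalInt
  if (!conserved && !any(grepl("clamped", object@flags)))
    return("per-locus counts must sum to totalInt unless clamping was flagged")
  TRUE
})

#' GenomeConfig: ground truth for one synthetic genome
#'
#' Describes a synthetic individual: per-locus allele counts, interlocus
#' gene-conversion tracts, functional point variants, sequencing depth and
#' seed, plus the region layout the genome lives in.
#'
#' @slot locusAlleles Named integer vector of allele counts per locus.
#' @slot conversionTracts data.frame with columns `donor`, `acceptor`,
#'   `start`, `end`, `nAlleles`: a tract converts `nAlleles` acceptor
#'   alleles to the donor's sequence over `[start, end]`, moving SUN
#'   carriage accordingly.
#' @slot pointVariants data.frame with columns `name`, `position`,
#'   `locus`, `nAlleles`, `refBase`, `altBase`. `locus` may be a single
#'   locus or `"NOTCH2NL"` for a variant spread over the NL paralogs by
#'   gene conversion.
#' @slot baseDepth Haploid-pair base depth: the single-copy (two-allele)
#'   region is simulated at this mean coverage.
#' @slot seed Integer seed; all draws derive from it.
#' @slot regions Region list as returned by [defaultRegions()].
#' @export
setClass("GenomeConfig", representation(
  locusAlleles = "integer",
  conversionTracts = "data.frame",
  pointVariants = "data.frame",
  baseDepth = "numeric",
  seed = "integer",
  regions = "list"
))

setValidity("GenomeConfig", function(object) {
  msg <- character(0)
  if (any(object@locusAlleles < 0)) msg <- c(msg, "allele counts must be >= 0")
  if (!all(.LOCI %in% names(object@locusAlleles)))
    msg <- c(msg, "locusAlleles must cover all five family loci")
  mc <- object@regions$multiCopy
  tr <- object@conversionTracts
  if (nrow(tr)) {
    if (any(tr$start > tr$end)) msg <- c(msg, "tract start must be <= end")
    if (any(tr$start < mc[1] | tr$end > mc[2]))
      msg <- c(msg, "tracts must lie within the multicopy region")
    bad <- tr$nAlleles > object@locusAlleles[tr$acceptor]
    if (any(bad))
      msg <- c(msg, "tract nAlleles may not exceed the acceptor allele count")
  }
  pv <- object@pointVariants
  if (nrow(pv)) {
    cap <- vapply(pv$locus, function(l) {
      if (l == "NOTCH2NL") sum(object@locusAlleles[.NL_LOCI])
      else object@locusAlleles[[l]]
    }, numeric(1))
    if (any(pv$nAlleles > cap))
      msg <- c(msg, "variant nAlleles may not exceed the carrying-locus allele count")
    if (any(pv$position < mc[1] | pv$position > mc[2]))
      msg <- c(msg, "variant positions must lie within the multicopy region")
  }
  if (object@baseDepth <= 0) msg <- c(msg, "baseDepth must be > 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ParalogPositionGroup: one variant's paralogous positions across loci
#'
#' Groups the hg38 positions of a single paralogous site across the family
#' loci, for frequency computation from multimapping-inclusive pileups.
#' Exactly one member (`variantLocus`) carries the variant allele on the
#' reference.
#'
#' @slot name Group/variant name.
#' @slot members data.frame with columns `locus`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`, `refBase`.
#' @slot variantLocus The member locus where the variant allele is
#'   annotated on the reference.
#' @export
setClass("ParalogPositionGroup", representation(
  name = "character",
  members = "data.frame",
  variantLocus = "character"
))

setValidity("ParalogPositionGroup", function(object) {
  if (nrow(object@members) < 2) return("a group needs >= 2 members")
  if (length(object@variantLocus) != 1 ||
      !object@variantLocus %in% object@members$locus)
    return("variantLocus must name exactly one member")
  TRUE
})
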