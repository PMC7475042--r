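# Canonical locus names, reference coordinates and generator layout shared
# across modules. All internal coordinates are 1-based inclusive; BED and
# bedGraph boundaries are converted at I/O time.

.LOCI <- c("NOTCH2", "NOTCH2NLR", "NOTCH2NLC", "NOTCH2NLA", "NOTCH2NLB")
.NL_LOCI <- setdiff(.LOCI, "NOTCH2")

# hg38 coordinates of the analysis regions on the masked reference: the
# NOTCH2 single-copy region (always diploid) and the NOTCH2+NOTCH2NL
# multicopy region onto which all family reads pile up. The SUN region is
# the maximal duplicon extent shared by all NOTCH2NL loci; its published
# end coordinate is truncated in print, so the multicopy-region end is used
# as the default and the region is configurable throughout.
.DEFAULT_CHROM <- "chr1"
.DEFAULT_SINGLE_COPY <- c(119908310L, 119989035L)
.DEFAULT_MULTI_COPY <- c(119990490L, 120087745L)
.DEFAULT_SUN_REGION <- c(119990474L, 120087745L)

# Functional-variant marker sites used by the synthetic generator, placed
# at fixed fractions of the multicopy region so that compact test genomes
# keep the same relative layout as full-scale ones. Fractions mirror the
# relative position of each variant within the real locus; sites without a
# published parent-locus (NOTCH2-projected) coordinate are synthetic
# placeholders -- only their presence, not their exact coordinate, matters
# to the estimators.
.VARIANT_FRACTIONS <- c(
  E258A      = 0.046,
  N232S      = 0.067,
  Exon2splice = 0.406,
  R113X      = 0.612,
  M40I       = 0.788,
  Exon1A     = 0.811,
  Exon1C     = 0.814
)

#' Default analysis regions
#'
#' The hg38 coordinates of the single-copy and multicopy regions used for
#' depth-ratio allele counting on the masked reference, and the SUN region
#' (maximal shared duplicon) used to restrict SUN markers.
#'
#' @return A list with elements `chrom` (character), and `singleCopy`,
#'   `multiCopy`, `sunRegion` (length-2 integer vectors of 1-based
#'   inclusive start/end).
#' @examples
#' defaultRegions()
#' @export
defaultRegions <- function() {
  list(
    chrom = .DEFAULT_CHROM,
    singleCopy = .DEFAULT_SINGLE_COPY,
    multiCopy = .DEFAULT_MULTI_COPY,
    sunRegion = .DEFAULT_SUN_REGION
  )
}

#' Compact analysis regions for small simulated genomes
#'
#' Returns a scaled-down region layout (same structure as
#' [defaultRegions()]) useful for fast simulations: a `width`-bp
#' single-copy region and a `width`-bp multicopy/SUN region separated by a
#' short gap.
#'
#' @param width Region width in bp (default 10000).
#' @return A region list as in [defaultRegions()].
#' @examples
#' compactRegions(5000)
#' @export
compactRegions <- function(width = 10000L) {
  width <- as.integer(width)
  stopifnot(width >= 100L)
  single <- c(1001L, 1000L + width)
  multi <- c(single[2] + 1001L, single[2] + 1000L + width)
  list(
    chrom = .DEFAULT_CHROM,
    singleCopy = single,
    multiCopy = multi,
    sunRegion = multi
  )
}

#' Default functional-variant marker positions
#'
#' Positions (in parent-locus coordinates) at which the synthetic
#' generator emits pileup rows for the functional variants tracked by the
#' dosage stage: the Exon1 classes (A-Low, C-X-low), the archaic missense
#' variants (M40I, N232S, E258A) and the deleterious R113* and exon-2
#' splice-acceptor variants. Each variant sits at a fixed fraction of the
#' multicopy region so compact and full-scale genomes share the layout.
#'
#' @param regions A region list as returned by [defaultRegions()] or
#'   [compactRegions()].
#' @return Named integer vector of 1-based positions.
#' @examples
#' defaultVariantPositions()
#' @export
defaultVariantPositions <- function(regions = defaultRegions()) {
  mc <- regions$multiCopy
  w <- mc[2] - mc[1] + 1L
  pos <- mc[1] + as.integer(round(.VARIANT_FRACTIONS * (w - 1L)))
  # resolve collisions deterministically
  while (anyDuplicated(pos)) {
    dup <- duplicated(pos)
    pos[dup] <- pos[dup] + 1L
  }
  setNames(pos, names(.VARIANT_FRACTIONS))
}
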