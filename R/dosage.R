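# Functional-variant allele dosage: archaic missense variants from read
# fractions, Exon1 class counts, and paralogous-position frequencies in
# the style of exome cohorts where reads map across all family loci.

#' Variant allele count from supporting-read fraction
#'
#' `frequency = AD / DP`; the allele count is the frequency scaled by the
#' total allele count and rounded half away from zero. The Altai
#' Neanderthal worked examples: 17 of 242 reads with 11 total alleles is
#' one allele; 28 of 177 is two.
#'
#' @param ad Reads supporting the variant.
#' @param dp Total reads at the site (> 0).
#' @param totalAlleles Total family allele count in the individual.
#' @return data.frame `frequency`, `alleleCount`, `readsSupporting`,
#'   `readsTotal` (vectorized over `ad`/`dp`).
#' @examples
#' alleleCountFromReads(17, 242, 11)
#' @export
alleleCountFromReads <- function(ad, dp, totalAlleles) {
  if (any(dp == 0)) stop("no coverage")
  stopifnot(all(ad >= 0), all(ad <= dp), totalAlleles >= 1)
  freq <- ad / dp
  data.frame(frequency = freq,
             alleleCount = as.integer(roundHalfAway(freq * totalAlleles)),
             readsSupporting = as.integer(ad),
             readsTotal = as.integer(dp))
}

#' Variant frequency from paralogous-position depths
#'
#' For exome-style data mapped to the unmasked reference, reads carrying
#' a variant pile up at the locus where the variant allele is annotated.
#' The frequency is that member's depth over the summed depth across all
#' paralogous positions (multimapping reads included upstream).
#'
#' @param depths Named numeric vector of read depths, one per group
#'   member locus.
#' @param group A [ParalogPositionGroup-class].
#' @return Frequency in `[0, 1]`, or `NA` when the total depth is zero.
#' @export
paralogGroupFrequency <- function(depths, group) {
  stopifnot(is(group, "ParalogPositionGroup"), all(depths >= 0))
  members <- group@members$locus
  stopifnot(all(members %in% names(depths)))
  d <- depths[members]
  tot <- sum(d)
  if (tot == 0) return(NA_real_)
  unname(d[[group@variantLocus]] / tot)
}

#' Exon1 variant class counts
#'
#' Counts the Exon1 A-(Low) and C-(X-low) variants from their pileup
#' rows (`round(frequency x total)`), and infers the B-(High) count as
#' the A/B pair total minus the A count, clamped at zero -- the B
#' configuration is the reference sequence, so it has no countable
#' variant read of its own.
#'
#' @param pileups Pileup data.frame ([parsePileupTable()] columns).
#' @param totalAllelesInt Combined family allele count.
#' @param abPairTotal Combined NOTCH2NLA+NOTCH2NLB allele count
#'   (modal 4).
#' @param positions Named positions of the `Exon1A` and `Exon1C` variant
#'   sites (defaults to the generator layout for the full-scale
#'   regions).
#' @return Named integer vector with elements `Exon1A`, `Exon1B`,
#'   `Exon1C`.
#' @export
exon1VariantCounts <- function(pileups, totalAllelesInt, abPairTotal,
                               positions = defaultVariantPositions()) {
  getSite <- function(nm) {
    row <- pileups[pileups$position == positions[[nm]], , drop = FALSE]
    if (!nrow(row)) stop(sprintf("missing pileup site for variant %s", nm))
    row[1, ]
  }
  a <- getSite("Exon1A")
  cc <- getSite("Exon1C")
  freq <- function(r) if (r$dp > 0) r$adAlt / r$dp else 0
  countA <- as.integer(roundHalfAway(freq(a) * totalAllelesInt))
  countC <- as.integer(roundHalfAway(freq(cc) * totalAllelesInt))
  countB <- max(0L, as.integer(abPairTotal) - countA)
  c(Exon1A = countA, Exon1B = countB, Exon1C = countC)
}

#' Built-in paralogous-position tables
#'
#' The three hg38 position groups used for exome-cohort frequency
#' analysis: the Exon1 A-(Low) variant (ATG>ATA, annotated on
#' NOTCH2NLA), the exon-2 splice-acceptor variant (annotated on
#' NOTCH2NLB) and the archaic N232S missense variant (AAT>AGT; absent
#' from the reference, conventionally attributed to NOTCH2NLB here).
#' Coordinates are 1-based inclusive; minus-strand members are reported
#' in plus-strand reference coordinates with the printed reference
#' bases.
#'
#' @return Named list of three [ParalogPositionGroup-class] objects:
#'   `Exon1A`, `Exon2splice`, `N232S`.
#' @examples
#' builtinPositionTables()$Exon1A
#' @export
builtinPositionTables <- function() {
  mk <- function(name, variantLocus, locus, start, end, strand, refBase) {
    new("ParalogPositionGroup", name = name,
        members = data.frame(locus = locus, chrom = "chr1", start = start,
                             end = end, strand = strand, refBase = refBase,
                             stringsAsFactors = FALSE),
        variantLocus = variantLocus)
  }
  list(
    Exon1A = mk(
      "Exon1A-Low", "NOTCH2NLA",
      locus = c("NOTCH2", "NOTCH2NLR", "NOTCH2NLA", "NOTCH2NLB", "NOTCH2NLC"),
      start = c(120069403L, 120724179L, 146228778L, 148679531L, 149390853L),
      end   = c(120069404L, 120724180L, 146228779L, 148679532L, 149390854L),
      strand = c("-", "+", "-", "-", "+"),
      refBase = c("ATG", "ATG", "ATA", "ATG", "ATG")),
    Exon2splice = mk(
      "Exon2B-Splice-mut", "NOTCH2NLB",
      locus = c("NOTCH2", "NOTCH2NLR", "NOTCH2NLA", "NOTCH2NLB", "NOTCH2NLC"),
      start = c(120029988L, 120763625L, 146189382L, 148640098L, 149430931L),
      end   = c(120029989L, 120763626L, 146189383L, 148640099L, 149430932L),
      strand = c("-", "+", "-", "-", "+"),
      refBase = c("T", "A", "T", "C", "A")),
    N232S = mk(
      "Nea-N232S", "NOTCH2NLB",
      locus = c("NOTCH2", "NOTCH2NLR", "NOTCH2NLA", "NOTCH2NLB", "NOTCH2NLC"),
      start = c(119997052L, 120793439L, 146156535L, 148607465L, 149463769L),
      end   = c(119997053L, 120793440L, 146156536L, 148607466L, 149463770L),
      strand = c("-", "+", "-", "-", "+"),
      refBase = c("T", "A", "T", "T", "A"))
  )
}

#' Export built-in position tables as BED
#'
#' @param groups List from [builtinPositionTables()].
#' @param path Optional output path.
#' @return BED lines (0-based half-open; name `group:locus:refBase`).
#' @export
writePositionTablesBed <- function(groups = builtinPositionTables(),
                                   path = NULL) {
  lines <- unlist(lapply(groups, function(g) {
    m <- g@members
    sprintf("%s\t%d\t%d\t%s:%s:%s\t0\t%s", m$chrom, m$start - 1L, m$end,
            g@name, m$locus, m$refBase, m$strand)
  }), use.names = FALSE)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
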