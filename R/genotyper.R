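# Per-paralog allele counts from SUN pileup frequencies.
#
# Pipeline: per-SUN frequencies (AD/DP) -> population filter against
# ambiguous/population-specific sites -> per-locus means scaled by the
# coverage-derived total -> subtraction + ratio split for the recently
# converted NOTCH2NLA/NOTCH2NLB pair -> NOTCH2>NOTCH2NLR gene-conversion
# correction.

#' Per-SUN allele frequencies for one sample
#'
#' Matches pileup rows to catalog records by (position, alternate base)
#' and computes `frequency = AD_alt / DP`. Zero-depth sites are reported
#' as missing (`NA`), not zero. Pileup rows whose alternate matches no
#' catalog record are skipped with a warning.
#'
#' @param pileups data.frame as returned by [parsePileupTable()] (columns
#'   `position`, `refBase`, `altBase`, `dp`, `adRef`, `adAlt`).
#' @param catalog A [SunCatalog-class].
#' @return data.frame with one row per matched SUN: `position`,
#'   `paralog`, `sunBase`, `dp`, `adAlt`, `frequency`.
#' @export
sunFrequencies <- function(pileups, catalog) {
  stopifnot(is(catalog, "SunCatalog"))
  suns <- sunTable(catalog)
  key <- function(p, b) paste(p, b, sep = ":")
  idx <- match(key(pileups$position, pileups$altBase),
               key(suns$position, suns$sunBase))
  unmatched <- is.na(idx) & pileups$position %in% suns$position
  if (any(unmatched))
    warning(sprintf("%d pileup row(s) with an alternate not in the catalog were skipped",
                    sum(unmatched)))
  hit <- !is.na(idx)
  p <- pileups[hit, , drop = FALSE]
  s <- suns[idx[hit], , drop = FALSE]
  freq <- ifelse(p$dp > 0, p$adAlt / p$dp, NA_real_)
  data.frame(position = p$position, paralog = s$paralog,
             sunBase = s$sunBase, dp = p$dp, adAlt = p$adAlt,
             frequency = freq, stringsAsFactors = FALSE)
}

#' Pool per-sample SUN frequencies into a cohort table
#'
#' @param freqList Named list of per-sample frequency tables from
#'   [sunFrequencies()].
#' @return Long data.frame with an added `sample` column.
#' @export
cohortSunFrequencies <- function(freqList) {
  stopifnot(length(freqList) >= 1, !is.null(names(freqList)))
  do.call(rbind, lapply(names(freqList), function(nm) {
    cbind(sample = nm, freqList[[nm]], stringsAsFactors = FALSE)
  }))
}

#' Population filter for SUN markers
#'
#' Retains a SUN iff the cohort summary (median by default) of its
#' observed frequency divided by its expected fraction exceeds the
#' threshold strictly. The expected fraction is the default carrying
#' alleles over the cohort-default total (2/10 unless overridden); sites
#' depressed across the population -- ambiguous positions or common SNPs
#' -- fall below the threshold and are excluded. A single-sample cohort
#' passes all SUNs with a warning.
#'
#' @param cohortFreqs Cohort table from [cohortSunFrequencies()].
#' @param catalog A [SunCatalog-class] to filter.
#' @param expectedFraction Expected per-SUN frequency (default `2/10`).
#' @param threshold Strict retention threshold on the normalized summary
#'   (default 0.67).
#' @param stat Cohort summary statistic, `"median"` or `"mean"`.
#' @return The retained [SunCatalog-class].
#' @export
populationFilter <- function(cohortFreqs, catalog, expectedFraction = 0.2,
                             threshold = 0.67, stat = c("median", "mean")) {
  stopifnot(is(catalog, "SunCatalog"), threshold > 0, threshold <= 1)
  stat <- match.arg(stat)
  nSamples <- length(unique(cohortFreqs$sample))
  if (nSamples < 2) {
    warning("single-sample cohort: population filter passes all SUNs")
    return(catalog)
  }
  sfun <- if (stat == "median") median else mean
  norm <- cohortFreqs$frequency / expectedFraction
  key <- paste(cohortFreqs$position, cohortFreqs$sunBase, sep = ":")
  summ <- tapply(norm, key, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) -Inf else sfun(v)
  })
  keep <- names(summ)[summ > threshold]
  df <- sunTable(catalog)
  df <- df[paste(df$position, df$sunBase, sep = ":") %in% keep, ,
           drop = FALSE]
  .newSunCatalog(df, catalog@parentName, catalog@paralogNames,
                 catalog@sunRegion,
                 chrom = as.character(seqnames(catalog@records))[1] %||%
                   .DEFAULT_CHROM)
}

#' Per-locus allele counts for one sample
#'
#' For NOTCH2, NOTCH2NLR and NOTCH2NLC (many SUNs each), the count is the
#' rounded product of the locus mean SUN frequency and the total allele
#' count. The remaining alleles are attributed to the NOTCH2NLA/NOTCH2NLB
#' pair -- too few SUNs and too much interlocus conversion for direct
#' estimation -- and split by the ratio of their mean SUN frequencies,
#' with largest-remainder rounding so A + B equals the remainder exactly.
#' A negative remainder (noisy data) clamps to zero with a flag.
#'
#' @param freqs Per-sample frequency table from [sunFrequencies()],
#'   restricted to retained SUNs.
#' @param totalAllelesInt Combined allele count from
#'   [totalAlleleCount()].
#' @return An [AlleleCountEstimate-class].
#' @export
locusAlleleCounts <- function(freqs, totalAllelesInt) {
  totalAllelesInt <- as.integer(totalAllelesInt)
  stopifnot(totalAllelesInt >= 2)
  meanFreq <- function(locus) {
    v <- freqs$frequency[freqs$paralog == locus]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }
  direct <- c("NOTCH2", "NOTCH2NLR", "NOTCH2NLC")
  mf <- vapply(direct, meanFreq, numeric(1))
  if (any(is.na(mf)))
    stop(sprintf("no retained SUNs for locus %s",
                 paste(direct[is.na(mf)], collapse = ", ")))
  counts <- as.integer(roundHalfAway(mf * totalAllelesInt))
  counts <- pmax(counts, 0L)
  names(counts) <- direct
  flags <- character(0)
  remaining <- totalAllelesInt - sum(counts)
  if (remaining < 0) {
    remaining <- 0L
    flags <- c(flags, "negative A/B remainder clamped to zero")
  }
  fA <- meanFreq("NOTCH2NLA")
  fB <- meanFreq("NOTCH2NLB")
  if (is.na(fA) && is.na(fB)) {
    flags <- c(flags, "no A/B SUNs: remainder split evenly")
    ab <- largestRemainder(c(NOTCH2NLA = 1, NOTCH2NLB = 1), remaining)
  } else {
    if (is.na(fA)) fA <- 0
    if (is.na(fB)) fB <- 0
    ab <- largestRemainder(c(NOTCH2NLA = fA, NOTCH2NLB = fB), remaining)
  }
  counts <- c(counts, ab)[.LOCI]
  new("AlleleCountEstimate", counts = counts, totalInt = totalAllelesInt,
      flags = flags)
}

#' Correct NOTCH2-to-NOTCH2NLR gene conversion
#'
#' Gene conversion of NOTCH2NLR alleles to NOTCH2 sequence inflates the
#' apparent NOTCH2 count and depresses NOTCH2NLR symmetrically. When the
#' estimate shows `NOTCH2 = 2 + k` and `NOTCH2NLR = 2 - k` (k >= 1), k
#' alleles are reassigned from NOTCH2 back to NOTCH2NLR; the total is
#' unchanged. A no-op when the pattern is absent.
#'
#' @param estimate An [AlleleCountEstimate-class].
#' @return The corrected [AlleleCountEstimate-class], flagged when the
#'   correction fired.
#' @export
n2nlrConversionCorrection <- function(estimate) {
  stopifnot(is(estimate, "AlleleCountEstimate"))
  counts <- estimate@counts
  k <- counts[["NOTCH2"]] - 2L
  if (k >= 1L && counts[["NOTCH2NLR"]] == 2L - k) {
    counts[["NOTCH2"]] <- 2L
    counts[["NOTCH2NLR"]] <- 2L
    return(new("AlleleCountEstimate", counts = counts,
               totalInt = estimate@totalInt,
               flags = c(estimate@flags, "N2>NLR conversion corrected")))
  }
  estimate
}
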