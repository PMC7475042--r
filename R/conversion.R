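# Interlocus gene-conversion profiling along per-SUN allele-count tracks.
#
# Each retained SUN yields a real-valued allele count (frequency x total);
# plotted along the locus these tracks reveal tracts where one paralog's
# sequence has overwritten another's. Cohort-level tracks use the median
# across samples.

#' Per-SUN allele-count track for one sample
#'
#' @param freqs Frequency table from [sunFrequencies()] (retained SUNs).
#' @param totalAllelesInt Combined allele count for the sample.
#' @return data.frame `position`, `paralog`, `countReal` sorted by
#'   position; missing (zero-depth) sites are omitted.
#' @export
perSunAlleleTrack <- function(freqs, totalAllelesInt) {
  keep <- !is.na(freqs$frequency)
  df <- data.frame(position = freqs$position[keep],
                   paralog = freqs$paralog[keep],
                   countReal = freqs$frequency[keep] * totalAllelesInt,
                   stringsAsFactors = FALSE)
  df[order(df$position), , drop = FALSE]
}

#' Median allele-count track across a cohort
#'
#' @param tracks Named list of per-sample tracks from
#'   [perSunAlleleTrack()].
#' @return data.frame `position`, `paralog`, `countMedian`.
#' @export
medianSunTrack <- function(tracks) {
  all <- do.call(rbind, tracks)
  key <- paste(all$position, all$paralog, sep = ":")
  med <- tapply(all$countReal, key, median)
  first <- !duplicated(key)
  df <- data.frame(position = all$position[first],
                   paralog = all$paralog[first],
                   countMedian = as.numeric(med[key[first]]),
                   stringsAsFactors = FALSE)
  df[order(df$position), , drop = FALSE]
}

#' Inferred complement track for the A/B paralog pair
#'
#' In the 5' region of the locus the B paralog has no SUNs of its own, so
#' its count is inferred from the A track: at each A-SUN position,
#' `B = pairTotal - A`, clamped at zero. With the modal pair total of 4,
#' an A count of 3 implies a B count of 1.
#'
#' @param trackA Track for the observed paralog (data.frame with
#'   `position` and `countReal` or `countMedian`).
#' @param pairTotal Combined A+B allele count for the sample (modal 4).
#' @param paralog Name to assign to the inferred track.
#' @return data.frame `position`, `paralog`, `countReal`.
#' @export
inferredComplementTrack <- function(trackA, pairTotal,
                                    paralog = "NOTCH2NLB") {
  if (missing(pairTotal) || is.null(pairTotal) || is.na(pairTotal))
    stop("pairTotal is required to infer the complement track")
  val <- if ("countReal" %in% names(trackA)) trackA$countReal
         else trackA$countMedian
  data.frame(position = trackA$position, paralog = paralog,
             countReal = pmax(0, pairTotal - val),
             stringsAsFactors = FALSE)
}

#' Call gene-conversion segments on a SUN track
#'
#' Maximal runs of at least `minRun` consecutive SUNs whose rounded
#' count deviates from `defaultCount` in the same direction are reported
#' as one segment; the magnitude is the median rounded deviation within
#' the run. The track should contain a single paralog.
#'
#' @param track data.frame with `position` and `countReal` (or
#'   `countMedian`), sorted by position.
#' @param defaultCount Expected allele count (default 2).
#' @param minRun Minimum run length in SUNs (default 3).
#' @return data.frame `start`, `end`, `paralog`, `direction`
#'   (`gain`/`loss`), `magnitude`; zero rows when no segment is called.
#' @export
callConversionSegments <- function(track, defaultCount = 2L, minRun = 3L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      paralog = character(0), direction = character(0),
                      magnitude = integer(0), stringsAsFactors = FALSE)
  if (!NROW(track)) return(empty)
  val <- if ("countReal" %in% names(track)) track$countReal
         else track$countMedian
  ord <- order(track$position)
  pos <- track$position[ord]
  paralog <- if ("paralog" %in% names(track)) track$paralog[ord][1] else NA_character_
  dev <- roundHalfAway(val[ord]) - defaultCount
  runs <- rle(sign(dev))
  out <- list()
  at <- 1L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    sgn <- runs$values[i]
    if (sgn != 0 && len >= minRun) {
      idx <- at:(at + len - 1L)
      out[[length(out) + 1L]] <- data.frame(
        start = pos[idx[1]], end = pos[idx[length(idx)]],
        paralog = paralog,
        direction = if (sgn > 0) "gain" else "loss",
        magnitude = as.integer(roundHalfAway(median(abs(dev[idx])))),
        stringsAsFactors = FALSE)
    }
    at <- at + len
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Write conversion segments as BED
#'
#' 0-based half-open intervals with name `paralog:direction:magnitude`.
#'
#' @param segments data.frame from [callConversionSegments()].
#' @param chrom Chromosome name.
#' @param path Optional output path.
#' @return The BED lines, invisibly if written.
#' @export
writeSegmentBed <- function(segments, chrom = .DEFAULT_CHROM, path = NULL) {
  lines <- sprintf("%s\t%d\t%d\t%s:%s:%d", chrom, segments$start - 1L,
                   segments$end, segments$paralog, segments$direction,
                   segments$magnitude)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
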