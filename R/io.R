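# Shared format readers and writers. Internal coordinates are 1-based
# inclusive; BED and bedGraph are 0-based half-open and convert at the
# boundary. Parsers report malformed rows with their line number.

.readLinesMaybe <- function(x) {
  if (length(x) == 1 && !grepl("[\t\n]", x) && file.exists(x))
    readLines(x)
  else as.character(x)
}

#' Parse a pileup table (bcftools-query dialect)
#'
#' Tab-separated columns CHROM, POS, REF, ALT, DP, AD_ref, AD_alt, one
#' row per site; '#'-prefixed header lines are tolerated.
#'
#' @param x File path or character vector of lines.
#' @return data.frame `chrom`, `position`, `refBase`, `altBase`, `dp`,
#'   `adRef`, `adAlt`.
#' @examples
#' parsePileupTable("chr1\t120000000\tA\tG\t100\t80\t20")
#' @export
parsePileupTable <- function(x) {
  lines <- .readLinesMaybe(x)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 7)
      stop(sprintf("line %d: expected 7 tab-separated columns, got %d",
                   i, length(f)))
    num <- suppressWarnings(as.numeric(f[5:7]))
    if (any(is.na(num)) || any(num < 0))
      stop(sprintf("line %d: DP/AD fields must be non-negative numbers", i))
    if (num[2] + num[3] > num[1])
      stop(sprintf("line %d: AD_ref + AD_alt exceeds DP", i))
    data.frame(chrom = f[1],
               position = as.integer(f[2]),
               refBase = f[3], altBase = f[4],
               dp = as.integer(num[1]), adRef = as.integer(num[2]),
               adAlt = as.integer(num[3]), stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(chrom = character(0), position = integer(0),
                      refBase = character(0), altBase = character(0),
                      dp = integer(0), adRef = integer(0),
                      adAlt = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a pileup table
#'
#' @param pileups data.frame as from [parsePileupTable()].
#' @param path Optional output path.
#' @return The lines, invisibly if written.
#' @export
writePileupTable <- function(pileups, path = NULL) {
  lines <- c("#CHROM\tPOS\tREF\tALT\tDP\tAD_REF\tAD_ALT",
             sprintf("%s\t%d\t%s\t%s\t%d\t%d\t%d", pileups$chrom,
                     pileups$position, pileups$refBase, pileups$altBase,
                     pileups$dp, pileups$adRef, pileups$adAlt))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Parse a bedGraph depth track
#'
#' bedGraph intervals are 0-based half-open with the value column giving
#' per-position depth; the line `chrom 0-based-start end depth` covers
#' 1-based positions `start+1 .. end`. Gaps between intervals are filled
#' with depth 0. A single chromosome is required.
#'
#' @param x File path or character vector of lines.
#' @return A [DepthTrack-class].
#' @export
parseBedgraph <- function(x) {
  lines <- .readLinesMaybe(x)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  if (!length(keep)) stop("no bedGraph records")
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 4)
  if (length(bad))
    stop(sprintf("line %d: expected 4 bedGraph columns, got %d",
                 keep[bad[1]], nfield[bad[1]]))
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  chrom <- unique(m[, 1])
  if (length(chrom) != 1) stop("bedGraph must cover a single chromosome")
  s <- suppressWarnings(as.integer(m[, 2]))
  e <- suppressWarnings(as.integer(m[, 3]))
  v <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(s) | is.na(e) | is.na(v) | e <= s | v < 0)
  if (length(bad))
    stop(sprintf("line %d: malformed bedGraph record", keep[bad[1]]))
  lo <- min(s) + 1L
  hi <- max(e)
  depth <- integer(hi - lo + 1L)
  for (i in seq_along(s)) {
    depth[(s[i] + 1L - lo + 1L):(e[i] - lo + 1L)] <- as.integer(v[i])
  }
  new("DepthTrack", chrom = chrom, start = lo, depth = depth)
}

#' Write a depth track as bedGraph
#'
#' Consecutive equal depths are collapsed into one 0-based half-open
#' interval.
#'
#' @param track A [DepthTrack-class].
#' @param path Optional output path.
#' @return The lines, invisibly if written.
#' @export
writeBedgraph <- function(track, path = NULL) {
  stopifnot(is(track, "DepthTrack"))
  r <- rle(track@depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lines <- sprintf("%s\t%d\t%d\t%d", track@chrom,
                   track@start + starts - 2L, track@start + ends - 1L,
                   r$values)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Parse BED intervals
#'
#' Generic BED reader: returns 1-based inclusive intervals plus the name
#' column when present.
#'
#' @param x File path or character vector of lines.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   `name` (NA when absent).
#' @export
parseBed <- function(x) {
  lines <- .readLinesMaybe(x)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("line %d: expected >= 3 BED columns, got %d", i, length(f)))
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stop(sprintf("line %d: malformed BED interval", i))
    data.frame(chrom = f[1], start = s + 1L, end = e,
               name = if (length(f) >= 4) f[4] else NA_character_,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
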