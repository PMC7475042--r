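# SUN catalog derivation and management.
#
# A SUN (singly unique nucleotide) is a variant carried by exactly one
# paralog of the family relative to the parent locus and to every other
# paralog; in a pooled pileup on the masked reference its allele frequency
# measures the carrying paralog's share of the family's alleles.

.newSunCatalog <- function(df, parentName, paralogNames, sunRegion,
                           chrom = .DEFAULT_CHROM) {
  if (nrow(df)) {
    df <- df[order(df$position, df$paralog), , drop = FALSE]
    gr <- GRanges(chrom, IRanges(df$position, width = 1L))
    mcols(gr)$paralog <- df$paralog
    mcols(gr)$parentBase <- df$parentBase
    mcols(gr)$sunBase <- df$sunBase
    mcols(gr)$kind <- df$kind
  } else {
    gr <- GRanges()
    mcols(gr)$paralog <- character(0)
    mcols(gr)$parentBase <- character(0)
    mcols(gr)$sunBase <- character(0)
    mcols(gr)$kind <- character(0)
  }
  new("SunCatalog", records = gr, parentName = parentName,
      paralogNames = paralogNames, sunRegion = as.integer(sunRegion))
}

#' SUN records as a data.frame
#'
#' @param catalog A [SunCatalog-class].
#' @return data.frame with columns `position`, `paralog`, `parentBase`,
#'   `sunBase`, `kind`.
#' @export
sunTable <- function(catalog) {
  stopifnot(is(catalog, "SunCatalog"))
  rec <- catalog@records
  data.frame(
    position = start(rec),
    paralog = mcols(rec)$paralog,
    parentBase = mcols(rec)$parentBase,
    sunBase = mcols(rec)$sunBase,
    kind = mcols(rec)$kind,
    stringsAsFactors = FALSE
  )
}

# collect variants of one paralog vs the parent from a global pairwise
# alignment, in parent coordinates, indels left-aligned.
.pairVariants <- function(parentChars, alnParent, alnParalog, anchorStart) {
  pa <- strsplit(alnParent, "")[[1]]
  sa <- strsplit(alnParalog, "")[[1]]
  out <- list()
  parentPos <- anchorStart - 1L
  i <- 1L
  n <- length(pa)
  leftAlignDel <- function(pos, del) {
    idx <- pos - anchorStart + 1L
    while (idx > 1L && parentChars[idx - 1L] == del[length(del)]) {
      del <- c(parentChars[idx - 1L], del[-length(del)])
      idx <- idx - 1L
      pos <- pos - 1L
    }
    list(pos = pos, seq = del)
  }
  leftAlignIns <- function(pos, ins) {
    # pos = preceding parent base; insertion sits between pos and pos+1
    idx <- pos - anchorStart + 1L
    while (idx >= 1L && parentChars[idx] == ins[length(ins)]) {
      ins <- c(parentChars[idx], ins[-length(ins)])
      idx <- idx - 1L
      pos <- pos - 1L
    }
    list(pos = max(pos, anchorStart - 1L), seq = ins)
  }
  while (i <= n) {
    if (pa[i] != "-" && sa[i] != "-") {
      parentPos <- parentPos + 1L
      if (pa[i] != sa[i]) {
        out[[length(out) + 1L]] <- data.frame(
          position = parentPos, parentBase = pa[i], sunBase = sa[i],
          kind = "SNV", stringsAsFactors = FALSE)
      }
      i <- i + 1L
    } else if (sa[i] == "-") {
      # deletion in the paralog: consume the run of deleted parent bases
      j <- i
      while (j <= n && sa[j] == "-") j <- j + 1L
      del <- pa[i:(j - 1L)]
      firstDeleted <- parentPos + 1L
      la <- leftAlignDel(firstDeleted, del)
      out[[length(out) + 1L]] <- data.frame(
        position = la$pos, parentBase = paste(la$seq, collapse = ""),
        sunBase = "-", kind = "deletion", stringsAsFactors = FALSE)
      parentPos <- parentPos + (j - i)
      i <- j
    } else {
      # insertion in the paralog, anchored at the preceding parent base
      j <- i
      while (j <= n && pa[j] == "-") j <- j + 1L
      ins <- sa[i:(j - 1L)]
      la <- leftAlignIns(parentPos, ins)
      out[[length(out) + 1L]] <- data.frame(
        position = la$pos, parentBase = "-",
        sunBase = paste(la$seq, collapse = ""), kind = "insertion",
        stringsAsFactors = FALSE)
      i <- j
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(position = integer(0), parentBase = character(0),
                  sunBase = character(0), kind = character(0),
                  stringsAsFactors = FALSE)
}

#' Derive SUNs from locus sequences
#'
#' Aligns each paralog sequence globally to the parent sequence and
#' reports, in parent coordinates, the positions at which exactly one
#' paralog differs from the parent and from all other paralogs. Variants
#' shared by two or more paralogs (same position and same alternate
#' allele) are excluded; two different alternate alleles at one position
#' can both be SUNs. Indels are left-aligned: a deletion is reported at
#' its first deleted parent base, an insertion at the preceding parent
#' base.
#'
#' @param parent Parent-locus sequence (character or
#'   [Biostrings::DNAString]), alphabet ACGTN.
#' @param paralogs Named character vector or
#'   [Biostrings::DNAStringSet] of paralog sequences.
#' @param parentName Name of the parent locus.
#' @param chrom Chromosome the parent anchor lives on.
#' @param anchorStart 1-based genomic position of the first parent base.
#' @param sunRegion Optional length-2 integer region restricting records;
#'   defaults to the full parent span.
#' @param minIdentity Minimum percent identity over the aligned length
#'   below which a paralog is rejected as unalignable (default 80).
#' @return A [SunCatalog-class].
#' @examples
#' deriveSuns("ACGTACGTAC", c(P1 = "ACTTACGTAC", P2 = "ACGTACGTAC"),
#'            anchorStart = 101)
#' @export
deriveSuns <- function(parent, paralogs, parentName = "NOTCH2",
                       chrom = .DEFAULT_CHROM, anchorStart = 1L,
                       sunRegion = NULL, minIdentity = 80) {
  parent <- as.character(parent)
  paralogs <- vapply(as.list(paralogs), as.character, character(1))
  if (length(parent) != 1 || !nzchar(parent) || length(paralogs) == 0 ||
      any(!nzchar(paralogs)))
    stop("no sequences")
  if (is.null(names(paralogs)) || any(!nzchar(names(paralogs))))
    stop("paralog sequences must be named")
  allseq <- c(parent, paralogs)
  if (any(grepl("[^ACGTN]", toupper(allseq))))
    stop("sequences must use the ACGTN alphabet")
  parent <- toupper(parent)
  paralogs <- toupper(paralogs)
  anchorStart <- as.integer(anchorStart)
  parentChars <- strsplit(parent, "")[[1]]
  span <- c(anchorStart, anchorStart + nchar(parent) - 1L)
  if (is.null(sunRegion)) sunRegion <- span

  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  pieces <- lapply(names(paralogs), function(nm) {
    aln <- pairwiseAlignment(DNAString(parent), DNAString(paralogs[[nm]]),
                             type = "global", substitutionMatrix = submat,
                             gapOpening = 2, gapExtension = 0.5)
    identity <- pid(aln, type = "PID1")
    if (identity < minIdentity)
      stop(sprintf("paralog '%s' cannot be aligned to the parent (identity %.1f%%)",
                   nm, identity))
    v <- .pairVariants(parentChars, as.character(alignedPattern(aln)),
                       as.character(alignedSubject(aln)), anchorStart)
    if (nrow(v)) v$paralog <- nm
    v
  })
  pieces <- pieces[vapply(pieces, nrow, integer(1)) > 0]
  df <- if (length(pieces)) do.call(rbind, pieces)
        else data.frame(position = integer(0), parentBase = character(0),
                        sunBase = character(0), kind = character(0),
                        paralog = character(0), stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- paste(df$position, df$kind, df$parentBase, df$sunBase)
    shared <- names(which(table(key) > 1))
    df <- df[!key %in% shared, , drop = FALSE]
    df <- df[df$position >= sunRegion[1] & df$position <= sunRegion[2], ,
             drop = FALSE]
  }
  .newSunCatalog(df, parentName, names(paralogs), sunRegion, chrom)
}

#' Restrict a SUN catalog to a region
#'
#' Keeps only records with `start <= position <= end`, preserving order,
#' and sets the catalog's SUN region to the given bounds.
#'
#' @param catalog A [SunCatalog-class].
#' @param start,end 1-based inclusive region bounds.
#' @return The filtered [SunCatalog-class].
#' @export
filterSunsByRegion <- function(catalog, start, end) {
  stopifnot(is(catalog, "SunCatalog"))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("inverted region: start must be <= end")
  df <- sunTable(catalog)
  df <- df[df$position >= start & df$position <= end, , drop = FALSE]
  .newSunCatalog(df, catalog@parentName, catalog@paralogNames,
                 c(start, end),
                 chrom = as.character(seqnames(catalog@records))[1] %||%
                   .DEFAULT_CHROM)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Write / read SUN records in BED format
#'
#' SUN records are stored as 0-based half-open BED intervals (a record at
#' 1-based position p becomes start `p-1`, end `p`) with the name column
#' encoding `paralog|parentBase|sunBase|kind`.
#'
#' @param catalog A [SunCatalog-class].
#' @param path Optional output path; if `NULL` the BED lines are
#'   returned.
#' @return `writeSunBed`: the BED lines, invisibly if written to `path`.
#' @export
writeSunBed <- function(catalog, path = NULL) {
  stopifnot(is(catalog, "SunCatalog"))
  df <- sunTable(catalog)
  chrom <- if (length(catalog@records))
    as.character(seqnames(catalog@records)) else character(0)
  lines <- sprintf("%s\t%d\t%d\t%s|%s|%s|%s", chrom, df$position - 1L,
                   df$position, df$paralog, df$parentBase, df$sunBase,
                   df$kind)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname writeSunBed
#' @param x BED file path or character vector of BED lines.
#' @param parentName,paralogNames,sunRegion Catalog metadata (not encoded
#'   in BED); `sunRegion` defaults to the span of the records.
#' @return `readSunBed`: a [SunCatalog-class].
#' @export
readSunBed <- function(x, parentName = "NOTCH2", paralogNames = NULL,
                       sunRegion = NULL) {
  lines <- .readLinesMaybe(x)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  recs <- lapply(which(keep), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4)
      stop(sprintf("line %d: expected >= 4 BED columns, got %d", i, length(f)))
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stop(sprintf("line %d: malformed BED interval", i))
    nm <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    if (length(nm) != 4)
      stop(sprintf("line %d: name must encode paralog|parentBase|sunBase|kind", i))
    data.frame(chrom = f[1], position = s + 1L, paralog = nm[1],
               parentBase = nm[2], sunBase = nm[3], kind = nm[4],
               stringsAsFactors = FALSE)
  })
  df <- if (length(recs)) do.call(rbind, recs)
        else data.frame(chrom = character(0), position = integer(0),
                        paralog = character(0), parentBase = character(0),
                        sunBase = character(0), kind = character(0),
                        stringsAsFactors = FALSE)
  if (is.null(paralogNames))
    paralogNames <- if (nrow(df)) sort(unique(df$paralog)) else character(0)
  if (is.null(sunRegion))
    sunRegion <- if (nrow(df)) range(df$position) else c(1L, 1L)
  chrom <- if (nrow(df)) df$chrom[1] else .DEFAULT_CHROM
  .newSunCatalog(df[, setdiff(names(df), "chrom"), drop = FALSE],
                 parentName, paralogNames, sunRegion, chrom)
}

#' Deterministic synthetic SUN catalog
#'
#' Builds a catalog of evenly spaced SNV-type SUNs per locus across the
#' SUN region, for use with the synthetic genome generator. Positions are
#' deterministic (no seed needed) and avoid the functional-variant marker
#' sites.
#'
#' @param nSuns Named integer vector: SUNs per locus. The defaults mirror
#'   the real marker density: many SUNs for NOTCH2/NOTCH2NLR/NOTCH2NLC,
#'   few for the recently diverged NOTCH2NLA/NOTCH2NLB pair.
#' @param regions Region list ([defaultRegions()] or [compactRegions()]).
#' @param avoid Positions to keep free of SUNs.
#' @return A [SunCatalog-class].
#' @examples
#' syntheticSunCatalog(regions = compactRegions())
#' @export
syntheticSunCatalog <- function(nSuns = c(NOTCH2 = 40L, NOTCH2NLR = 40L,
                                          NOTCH2NLC = 40L, NOTCH2NLA = 6L,
                                          NOTCH2NLB = 6L),
                                regions = defaultRegions(),
                                avoid = defaultVariantPositions(regions)) {
  sr <- regions$sunRegion
  w <- sr[2] - sr[1] + 1L
  stopifnot(w > sum(nSuns) * 2)
  bases <- c("A", "C", "G", "T")
  used <- as.integer(avoid)
  rows <- list()
  for (k in seq_along(nSuns)) {
    locus <- names(nSuns)[k]
    n <- nSuns[[k]]
    if (n == 0) next
    pos <- sr[1] + as.integer(floor((seq_len(n) - 0.5) * w / n)) + k
    pos <- pmin(pos, sr[2])
    for (j in seq_along(pos)) {
      while (pos[j] %in% used) pos[j] <- pos[j] + 1L
      used <- c(used, pos[j])
    }
    pb <- bases[(pos %% 4L) + 1L]
    sb <- bases[((pos + 1L) %% 4L) + 1L]
    rows[[k]] <- data.frame(position = pos, paralog = locus,
                            parentBase = pb, sunBase = sb, kind = "SNV",
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  .newSunCatalog(df, "NOTCH2", names(nSuns)[nSuns > 0], sr, regions$chrom)
}
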