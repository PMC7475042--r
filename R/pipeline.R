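# End-to-end per-sample orchestration: depth-ratio total, SUN genotyping
# with corrections, variant dosage, conversion tracks and segments.

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the per-sample pipeline.
#'
#' @param regions Region list ([defaultRegions()] or
#'   [compactRegions()]).
#' @param catalog A [SunCatalog-class] of SUN markers.
#' @param repeatMask Optional two-column matrix of masked (repeat)
#'   intervals, subtracted from both depth regions.
#' @param threshold Population-filter threshold in `(0, 1]`
#'   (default 0.67, strict).
#' @param filterStat Cohort summary for the population filter
#'   (`"median"` or `"mean"`).
#' @param expectedFraction Expected per-SUN frequency for the filter
#'   (default `2/10`).
#' @param defaultCount,minRun Conversion-segment parameters.
#' @param variantPositions Named positions of the functional-variant
#'   sites.
#' @return A list of validated parameters.
#' @export
pipelineConfig <- function(regions = defaultRegions(),
                           catalog = syntheticSunCatalog(regions = regions),
                           repeatMask = NULL,
                           threshold = 0.67,
                           filterStat = "median",
                           expectedFraction = 0.2,
                           defaultCount = 2L, minRun = 3L,
                           variantPositions = defaultVariantPositions(regions)) {
  stopifnot(threshold > 0, threshold <= 1,
            regions$singleCopy[1] <= regions$singleCopy[2],
            regions$multiCopy[1] <= regions$multiCopy[2])
  list(regions = regions, catalog = catalog, repeatMask = repeatMask,
       threshold = threshold, filterStat = filterStat,
       expectedFraction = expectedFraction, defaultCount = defaultCount,
       minRun = minRun, variantPositions = variantPositions)
}

#' Run the per-sample pipeline
#'
#' Stages, in order: (1) mean depth over the repeat-masked single-copy
#' and multicopy regions and the depth-ratio total allele count; (2)
#' per-SUN frequencies, population filter (pass-all with a warning when
#' no cohort table is supplied), per-locus allele counts and the
#' NOTCH2-to-NOTCH2NLR conversion correction; (3) Exon1 class counts and
#' per-variant dosages at the configured variant sites; (4) the per-SUN
#' allele-count track and gene-conversion segments per paralog.
#'
#' @param depth A [DepthTrack-class] or bedGraph file path.
#' @param pileups A pileup data.frame or file path
#'   ([parsePileupTable()] dialect).
#' @param config List from [pipelineConfig()].
#' @param cohortFreqs Optional cohort frequency table
#'   ([cohortSunFrequencies()]) for the population filter.
#' @param sampleId Sample label carried into the report.
#' @return List of class `sunCNReport`: `sampleId`, `total`
#'   ([TotalAlleleEstimate-class]), `alleleCounts`
#'   ([AlleleCountEstimate-class]), `exon1` (named counts), `dosages`
#'   (data.frame), `track`, `segments`, `retainedSuns`.
#' @export
runPipeline <- function(depth, pileups, config = pipelineConfig(),
                        cohortFreqs = NULL, sampleId = "sample") {
  if (is.character(depth)) depth <- parseBedgraph(depth)
  if (is.character(pileups)) pileups <- parsePileupTable(pileups)
  if (!NROW(pileups)) stop("pileup table contains no records")

  r <- config$regions
  singleMean <- meanDepth(depth, regionSet(r$singleCopy, config$repeatMask))
  multiMean <- meanDepth(depth, regionSet(r$multiCopy, config$repeatMask))
  total <- totalAlleleCount(multiMean, singleMean)

  freqs <- sunFrequencies(pileups, config$catalog)
  retained <- if (is.null(cohortFreqs)) {
    suppressWarnings(populationFilter(
      cohortSunFrequencies(setNames(list(freqs), sampleId)),
      config$catalog, expectedFraction = config$expectedFraction,
      threshold = config$threshold, stat = config$filterStat))
  } else {
    populationFilter(cohortFreqs, config$catalog,
                     expectedFraction = config$expectedFraction,
                     threshold = config$threshold,
                     stat = config$filterStat)
  }
  retainedFreqs <- sunFrequencies(pileups, retained)
  counts <- locusAlleleCounts(retainedFreqs, total@totalInt)
  counts <- n2nlrConversionCorrection(counts)

  abPairTotal <- sum(alleleCounts(counts)[c("NOTCH2NLA", "NOTCH2NLB")])
  exon1 <- tryCatch(
    exon1VariantCounts(pileups, total@totalInt, abPairTotal,
                       positions = config$variantPositions),
    error = function(e) {
      if (grepl("missing pileup site", conditionMessage(e))) NULL
      else stop(e)
    })
  vp <- config$variantPositions
  dosages <- do.call(rbind, lapply(names(vp), function(nm) {
    row <- pileups[pileups$position == vp[[nm]], , drop = FALSE]
    if (!nrow(row) || row$dp[1] == 0) return(NULL)
    cbind(variant = nm,
          alleleCountFromReads(row$adAlt[1], row$dp[1], total@totalInt))
  }))

  track <- perSunAlleleTrack(retainedFreqs, total@totalInt)
  segments <- do.call(rbind, lapply(unique(track$paralog), function(p) {
    callConversionSegments(track[track$paralog == p, , drop = FALSE],
                           defaultCount = config$defaultCount,
                           minRun = config$minRun)
  }))

  structure(list(sampleId = sampleId, total = total,
                 alleleCounts = counts, exon1 = exon1, dosages = dosages,
                 track = track, segments = segments,
                 retainedSuns = length(retained)),
            class = "sunCNReport")
}

#' @export
print.sunCNReport <- function(x, ...) {
  cat(sprintf("sunCN report for %s\n", x$sampleId))
  cat(sprintf("  total alleles: %d (ratio %.3f, real %.2f)\n",
              x$total@totalInt, x$total@ratio, x$total@totalReal))
  show(x$alleleCounts)
  cat("  Exon1 classes:",
      paste(sprintf("%s=%d", names(x$exon1), x$exon1), collapse = " "),
      "\n")
  if (!is.null(x$dosages) && nrow(x$dosages)) {
    nz <- x$dosages[x$dosages$alleleCount > 0, , drop = FALSE]
    if (nrow(nz))
      cat("  variant dosages:",
          paste(sprintf("%s=%d", nz$variant, nz$alleleCount),
                collapse = " "), "\n")
  }
  if (!is.null(x$segments) && NROW(x$segments))
    cat(sprintf("  %d conversion segment(s) called\n", nrow(x$segments)))
  invisible(x)
}

#' Write a pipeline report as TSV
#'
#' One key-value section per stage; machine-readable and diff-stable.
#'
#' @param report A `sunCNReport` from [runPipeline()].
#' @param path Optional output path.
#' @return The lines, invisibly if written.
#' @export
writeReportTsv <- function(report, path = NULL) {
  counts <- alleleCounts(report$alleleCounts)
  lines <- c(
    sprintf("sample\t%s", report$sampleId),
    sprintf("ratio\t%.6f", report$total@ratio),
    sprintf("total_real\t%.6f", report$total@totalReal),
    sprintf("total_int\t%d", report$total@totalInt),
    sprintf("count_%s\t%d", names(counts), counts),
    sprintf("exon1_%s\t%d", names(report$exon1), report$exon1),
    sprintf("flags\t%s",
            paste(estimateFlags(report$alleleCounts), collapse = ";")),
    sprintf("retained_suns\t%d", report$retainedSuns))
  if (!is.null(report$dosages) && nrow(report$dosages))
    lines <- c(lines, sprintf("dosage_%s\t%d", report$dosages$variant,
                              report$dosages$alleleCount))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
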