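# Ground-truthed synthetic genomes: depth tracks and pileup tables with
# the statistical structure the estimators assume. Depth is Poisson with
# mean proportional to the local allele count; allele depths at SUN and
# variant sites are binomial in the carrying-allele fraction, modified by
# gene-conversion tracts. Depth is simulated per position, not per read:
# the inference consumes only DP/AD, so read-level simulation would add
# nothing testable.

.emptyTracts <- function() {
  data.frame(donor = character(0), acceptor = character(0),
             start = integer(0), end = integer(0), nAlleles = integer(0),
             stringsAsFactors = FALSE)
}

.emptyVariants <- function() {
  data.frame(name = character(0), position = integer(0),
             locus = character(0), nAlleles = integer(0),
             refBase = character(0), altBase = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a synthetic genome configuration
#'
#' @param locusAlleles Named integer vector of allele counts per locus
#'   (default two alleles each).
#' @param conversionTracts data.frame (`donor`, `acceptor`, `start`,
#'   `end`, `nAlleles`); a tract converts `nAlleles` acceptor alleles to
#'   donor sequence over the interval, so acceptor SUN carriage drops by
#'   `nAlleles` and donor SUN carriage rises by `nAlleles` inside it.
#' @param pointVariants data.frame (`name`, `position`, `locus`,
#'   `nAlleles`, `refBase`, `altBase`); `locus = "NOTCH2NL"` marks a
#'   variant spread over the NL paralogs.
#' @param baseDepth Mean depth of the two-allele single-copy region
#'   (default 30).
#' @param seed Integer seed.
#' @param regions Region list ([defaultRegions()] or
#'   [compactRegions()]).
#' @return A [GenomeConfig-class].
#' @examples
#' genomeConfig(baseDepth = 30, seed = 7)
#' @export
genomeConfig <- function(locusAlleles = setNames(rep(2L, 5), .LOCI),
                         conversionTracts = .emptyTracts(),
                         pointVariants = .emptyVariants(),
                         baseDepth = 30, seed = 1L,
                         regions = defaultRegions()) {
  la <- setNames(as.integer(locusAlleles), names(locusAlleles))
  new("GenomeConfig", locusAlleles = la,
      conversionTracts = conversionTracts,
      pointVariants = pointVariants, baseDepth = as.numeric(baseDepth),
      seed = as.integer(seed), regions = regions)
}

.presetNames <- c("modern_human_standard", "neanderthal_altai_like",
                  "denisova3_like")

#' Preset genome configurations
#'
#' Three configurations observed in sequenced genomes:
#' \describe{
#'   \item{modern_human_standard}{Ten alleles, two per locus; both
#'     NOTCH2NLC alleles carry the Exon1 C-(X-low) variant and the two
#'     NOTCH2NLA alleles carry the Exon1 A-(Low) variant.}
#'   \item{neanderthal_altai_like}{Eleven alleles: two NOTCH2 plus nine
#'     NOTCH2NL (an extra A/B-pair allele), a NOTCH2-to-NOTCH2NLR
#'     conversion tract over the whole SUN region on one allele, the
#'     M40I variant on one allele and N232S on two.}
#'   \item{denisova3_like}{Eight alleles with a homozygous NOTCH2NLR
#'     deletion; all six NOTCH2NL alleles carry the Exon1 C-(X-low)
#'     variant, and E258A sits on two alleles.}
#' }
#'
#' @param name Preset name.
#' @param baseDepth,seed,regions Passed to [genomeConfig()].
#' @return A [GenomeConfig-class].
#' @examples
#' preset("modern_human_standard")
#' @export
preset <- function(name, baseDepth = 30, seed = 1L,
                   regions = defaultRegions()) {
  if (!is.character(name) || length(name) != 1 || !name %in% .presetNames)
    stop("unknown preset; available: ", paste(.presetNames, collapse = ", "))
  vp <- defaultVariantPositions(regions)
  variant <- function(nm, locus, n) {
    data.frame(name = nm, position = vp[[nm]], locus = locus,
               nAlleles = as.integer(n), refBase = "A", altBase = "G",
               stringsAsFactors = FALSE)
  }
  if (name == "modern_human_standard") {
    genomeConfig(
      locusAlleles = setNames(c(2L, 2L, 2L, 2L, 2L), .LOCI),
      pointVariants = rbind(
        variant("Exon1A", "NOTCH2NLA", 2),
        variant("Exon1C", "NOTCH2NLC", 2),
        variant("M40I", "NOTCH2NL", 0),
        variant("N232S", "NOTCH2NL", 0),
        variant("E258A", "NOTCH2NL", 0),
        variant("R113X", "NOTCH2NLB", 0),
        variant("Exon2splice", "NOTCH2NLB", 0)),
      baseDepth = baseDepth, seed = seed, regions = regions)
  } else if (name == "neanderthal_altai_like") {
    mc <- regions$multiCopy
    genomeConfig(
      locusAlleles = setNames(c(2L, 2L, 2L, 3L, 2L), .LOCI),
      conversionTracts = data.frame(
        donor = "NOTCH2", acceptor = "NOTCH2NLR",
        start = mc[1], end = mc[2], nAlleles = 1L,
        stringsAsFactors = FALSE),
      pointVariants = rbind(
        variant("Exon1A", "NOTCH2NLA", 3),
        variant("Exon1C", "NOTCH2NLC", 2),
        variant("M40I", "NOTCH2NL", 1),
        variant("N232S", "NOTCH2NL", 2),
        variant("E258A", "NOTCH2NL", 0),
        variant("R113X", "NOTCH2NLB", 0),
        variant("Exon2splice", "NOTCH2NLB", 0)),
      baseDepth = baseDepth, seed = seed, regions = regions)
  } else {
    genomeConfig(
      locusAlleles = setNames(c(2L, 0L, 2L, 2L, 2L), .LOCI),
      pointVariants = rbind(
        variant("Exon1A", "NOTCH2NLA", 0),
        variant("Exon1C", "NOTCH2NL", 6),
        variant("M40I", "NOTCH2NL", 0),
        variant("N232S", "NOTCH2NL", 0),
        variant("E258A", "NOTCH2NL", 2),
        variant("R113X", "NOTCH2NLB", 0),
        variant("Exon2splice", "NOTCH2NLB", 0)),
      baseDepth = baseDepth, seed = seed, regions = regions)
  }
}

# total alleles whose duplicon spans a multicopy position; duplicons
# default to the full multicopy region for every locus, so this is the
# family total there and 2 (diploid) elsewhere.
.localAlleles <- function(config, pos) {
  mc <- config@regions$multiCopy
  ifelse(pos >= mc[1] & pos <= mc[2], sum(config@locusAlleles), 2L)
}

#' Simulate a per-position depth track
#'
#' Depth at each position is Poisson with mean
#' `baseDepth * localAlleleCount / 2`: the single-copy region always
#' represents two alleles, the multicopy region the family total.
#' The track spans from the single-copy start to the multicopy end.
#' Reproducible: the draw stream derives from the config seed.
#'
#' @param config A [GenomeConfig-class].
#' @return A [DepthTrack-class].
#' @export
simulateDepth <- function(config) {
  stopifnot(is(config, "GenomeConfig"), config@baseDepth > 0)
  r <- config@regions
  lo <- r$singleCopy[1]
  hi <- r$multiCopy[2]
  pos <- seq.int(lo, hi)
  lam <- config@baseDepth * .localAlleles(config, pos) / 2
  set.seed(deriveSeed(config@seed, 1L))
  new("DepthTrack", chrom = r$chrom, start = lo,
      depth = as.integer(rpois(length(pos), lam)))
}

# SUN carriage per catalog record under the config's truth: the carrying
# paralog's allele count, minus alleles converted away by tracts covering
# the site, plus alleles converted in when the paralog is the donor.
.sunCarriage <- function(config, positions, paralogs) {
  carry <- as.numeric(config@locusAlleles[paralogs])
  tr <- config@conversionTracts
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      inTract <- positions >= tr$start[i] & positions <= tr$end[i]
      carry[inTract & paralogs == tr$acceptor[i]] <-
        carry[inTract & paralogs == tr$acceptor[i]] - tr$nAlleles[i]
      carry[inTract & paralogs == tr$donor[i]] <-
        carry[inTract & paralogs == tr$donor[i]] + tr$nAlleles[i]
    }
  }
  pmin(pmax(carry, 0), sum(config@locusAlleles))
}

#' Simulate a pileup table at SUN and variant sites
#'
#' At each site, total depth is Poisson with mean
#' `baseDepth * total / 2` and the variant-supporting depth is binomial
#' with success probability `carrying / total`, where `carrying` is the
#' number of alleles carrying the SUN (locus allele count modified by any
#' conversion tract covering the site) or the point variant.
#'
#' @param config A [GenomeConfig-class].
#' @param catalog A [SunCatalog-class]; positions must lie within the
#'   multicopy region.
#' @return Pileup data.frame (`chrom`, `position`, `refBase`, `altBase`,
#'   `dp`, `adRef`, `adAlt`) sorted by position.
#' @export
simulatePileups <- function(config, catalog) {
  stopifnot(is(config, "GenomeConfig"), is(catalog, "SunCatalog"))
  mc <- config@regions$multiCopy
  suns <- sunTable(catalog)
  if (nrow(suns) && any(suns$position < mc[1] | suns$position > mc[2]))
    stop("catalog positions outside the simulated multicopy region")
  pv <- config@pointVariants
  if (nrow(pv) && any(pv$position < mc[1] | pv$position > mc[2]))
    stop("variant position outside the simulated region")
  total <- sum(config@locusAlleles)
  sites <- rbind(
    data.frame(position = suns$position, refBase = suns$parentBase,
               altBase = suns$sunBase,
               carrying = .sunCarriage(config, suns$position, suns$paralog),
               stringsAsFactors = FALSE),
    data.frame(position = pv$position, refBase = pv$refBase,
               altBase = pv$altBase, carrying = as.numeric(pv$nAlleles),
               stringsAsFactors = FALSE))
  sites <- sites[order(sites$position), , drop = FALSE]
  set.seed(deriveSeed(config@seed, 2L))
  dp <- rpois(nrow(sites), config@baseDepth * total / 2)
  prob <- if (total > 0) sites$carrying / total else rep(0, nrow(sites))
  adAlt <- rbinom(nrow(sites), dp, prob)
  data.frame(chrom = config@regions$chrom, position = sites$position,
             refBase = sites$refBase, altBase = sites$altBase, dp = dp,
             adRef = dp - adAlt, adAlt = adAlt, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Simulate one individual (depth track + pileup table + truth)
#'
#' @param config A [GenomeConfig-class].
#' @param catalog A [SunCatalog-class]; defaults to the deterministic
#'   synthetic catalog over the config's regions.
#' @return List with elements `depth` ([DepthTrack-class]), `pileups`
#'   (data.frame) and `truth` (the config).
#' @export
simulateIndividual <- function(config,
                               catalog = syntheticSunCatalog(
                                 regions = config@regions)) {
  list(depth = simulateDepth(config),
       pileups = simulatePileups(config, catalog),
       truth = config)
}

#' Simulate a seeded cohort
#'
#' Draws each individual's preset from `presetMix` and simulates it with
#' a per-individual seed derived deterministically from the cohort seed
#' and the individual index.
#'
#' @param n Number of individuals.
#' @param presetMix Named numeric vector of preset probabilities
#'   (default: all `modern_human_standard`).
#' @param variantFreqs Optional named vector of population allele
#'   frequencies for point variants: each individual's carrier count is
#'   drawn Binomial(4, f) over the modal A/B pair total and overrides
#'   the preset's entry for that variant (carried across the NL
#'   paralogs).
#' @param baseDepth Per-individual base depth.
#' @param seed Cohort seed.
#' @param regions Region list.
#' @param catalog Shared [SunCatalog-class].
#' @return List with `individuals` (named list from
#'   [simulateIndividual()]) and `truth` (data.frame: sample, preset,
#'   per-locus truth counts and total).
#' @export
simulateCohort <- function(n, presetMix = c(modern_human_standard = 1),
                           variantFreqs = NULL,
                           baseDepth = 30, seed = 1L,
                           regions = defaultRegions(),
                           catalog = syntheticSunCatalog(regions = regions)) {
  stopifnot(n >= 1, all(presetMix >= 0), sum(presetMix) > 0,
            all(names(presetMix) %in% .presetNames))
  if (!is.null(variantFreqs))
    stopifnot(!is.null(names(variantFreqs)),
              all(variantFreqs >= 0 & variantFreqs <= 1))
  set.seed(deriveSeed(seed, 0L))
  picks <- sample(names(presetMix), n, replace = TRUE,
                  prob = presetMix / sum(presetMix))
  carriers <- if (is.null(variantFreqs)) NULL else
    matrix(unlist(lapply(variantFreqs, function(f) rbinom(n, 4L, f))),
           nrow = n, dimnames = list(NULL, names(variantFreqs)))
  ids <- sprintf("sample%03d", seq_len(n))
  individuals <- lapply(seq_len(n), function(i) {
    cfg <- preset(picks[i], baseDepth = baseDepth,
                  seed = deriveSeed(seed, i), regions = regions)
    if (!is.null(carriers)) {
      pv <- cfg@pointVariants
      for (v in colnames(carriers)) {
        hit <- pv$name == v
        pv$nAlleles[hit] <- carriers[i, v]
        pv$locus[hit] <- "NOTCH2NL"
      }
      cfg@pointVariants <- pv
      validObject(cfg)
    }
    simulateIndividual(cfg, catalog = catalog)
  })
  names(individuals) <- ids
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    la <- individuals[[i]]$truth@locusAlleles
    cbind(data.frame(sample = ids[i], preset = picks[i],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(la)),
          data.frame(total = sum(la)))
  }))
  list(individuals = individuals, truth = truth)
}

#' Write a cohort truth table as TSV
#'
#' @param cohort List from [simulateCohort()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTruthTable <- function(cohort, path) {
  write.table(cohort$truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
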