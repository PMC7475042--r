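# SUN-frequency genotyping: filtering, per-locus counts, corrections.

test_that("SUN frequencies are AD/DP with zero-depth sites marked missing", {
  regions <- toyRegions()
  cat <- toyCatalog(regions)
  st <- sunTable(cat)
  p <- data.frame(chrom = "chr1", position = st$position[1:3],
                  refBase = st$parentBase[1:3], altBase = st$sunBase[1:3],
                  dp = c(100L, 0L, 50L), adRef = c(80L, 0L, 40L),
                  adAlt = c(20L, 0L, 10L), stringsAsFactors = FALSE)
  f <- sunFrequencies(p, cat)
  expect_equal(f$frequency, c(0.20, NA, 0.20))

  # a pileup alternate not in the catalog is skipped with a warning
  p$altBase[3] <- st$parentBase[3]
  expect_warning(f2 <- sunFrequencies(p, cat), "skipped")
  expect_equal(nrow(f2), 2)

  # 50 random sites equal the direct division oracle
  set.seed(5)
  idx <- sample(nrow(st), 50)
  dp <- rpois(50, 150) + 1L
  ad <- rbinom(50, dp, 0.2)
  pr <- data.frame(chrom = "chr1", position = st$position[idx],
                   refBase = st$parentBase[idx], altBase = st$sunBase[idx],
                   dp = dp, adRef = dp - ad, adAlt = ad,
                   stringsAsFactors = FALSE)
  fr <- sunFrequencies(pr, cat)
  expect_equal(fr$frequency[match(st$position[idx], fr$position)], ad / dp)
})

test_that("population filter is strict at the threshold and spares clean SUNs", {
  regions <- toyRegions()
  cat <- toyCatalog(regions)
  st <- sunTable(cat)
  expected <- 0.2
  mkSample <- function(freqs) {
    data.frame(position = st$position, paralog = st$paralog,
               sunBase = st$sunBase, dp = 100L,
               adAlt = as.integer(round(freqs * 100)), frequency = freqs,
               stringsAsFactors = FALSE)
  }
  base <- rep(expected, nrow(st))
  # site 1: normalized frequency exactly 0.67 -> excluded (strict >)
  # site 2: normalized 0.68 -> retained
  # site 3: a common SNP depressed to normalized 0.5 in every sample
  f1 <- base; f1[1] <- 0.67 * expected; f1[2] <- 0.68 * expected
  f1[3] <- 0.5 * expected
  cohort <- cohortSunFrequencies(list(s1 = mkSample(f1), s2 = mkSample(f1),
                                      s3 = mkSample(f1)))
  kept <- populationFilter(cohort, cat, expectedFraction = expected)
  keptPos <- sunTable(kept)$position
  expect_false(st$position[1] %in% keptPos)
  expect_true(st$position[2] %in% keptPos)
  expect_false(st$position[3] %in% keptPos)
  expect_equal(length(kept), nrow(st) - 2)

  # a SUN at normalized frequency 1.0 in all samples is never removed
  set.seed(21)
  for (i in 1:5) {
    noise <- matrix(runif(3 * nrow(st), 0, expected), nrow = 3)
    noise[, 1] <- expected # site 1 clean everywhere
    cohort <- cohortSunFrequencies(list(a = mkSample(noise[1, ]),
                                        b = mkSample(noise[2, ]),
                                        c = mkSample(noise[3, ])))
    kept <- populationFilter(cohort, cat, expectedFraction = expected)
    expect_true(st$position[1] %in% sunTable(kept)$position)
  }

  # single-sample cohorts pass everything, with a warning
  single <- cohortSunFrequencies(list(only = mkSample(f1)))
  expect_warning(all <- populationFilter(single, cat), "single-sample")
  expect_equal(length(all), nrow(st))
})

test_that("per-locus counts reproduce the worked configurations", {
  # modal: total 10, mean frequencies 0.2 for the direct loci, A:B 1:1
  f <- freqTable(
    paralog = c(rep("NOTCH2", 3), rep("NOTCH2NLR", 3), rep("NOTCH2NLC", 3),
                "NOTCH2NLA", "NOTCH2NLB"),
    frequency = c(rep(0.2, 9), 0.2, 0.2))
  est <- locusAlleleCounts(f, 10L)
  expect_equal(unname(alleleCounts(est)), rep(2L, 5))
  expect_equal(totalAlleles(est), 10L)

  # homozygous NOTCH2NLR deletion: frequency 0 -> count 0 at total 8
  f0 <- freqTable(
    paralog = c("NOTCH2", "NOTCH2NLR", "NOTCH2NLC", "NOTCH2NLA", "NOTCH2NLB"),
    frequency = c(0.25, 0, 0.25, 0.25, 0.25))
  est0 <- locusAlleleCounts(f0, 8L)
  expect_equal(alleleCounts(est0)[["NOTCH2NLR"]], 0L)
  expect_equal(sum(alleleCounts(est0)), 8L)

  # A/B ratio split: total 10, direct loci take 6, A 0.3 vs B 0.1 -> 3 and 1
  fab <- freqTable(
    paralog = c("NOTCH2", "NOTCH2NLR", "NOTCH2NLC", "NOTCH2NLA", "NOTCH2NLB"),
    frequency = c(0.2, 0.2, 0.2, 0.3, 0.1))
  ab <- alleleCounts(locusAlleleCounts(fab, 10L))
  expect_equal(ab[["NOTCH2NLA"]], 3L)
  expect_equal(ab[["NOTCH2NLB"]], 1L)

  # a required locus without retained SUNs is an error naming the locus
  expect_error(
    locusAlleleCounts(freqTable(c("NOTCH2", "NOTCH2NLC"), c(0.2, 0.2)), 10L),
    "NOTCH2NLR")
})

test_that("per-locus counts always sum to the total (conservation)", {
  set.seed(9)
  for (i in 1:200) {
    total <- sample(6:12, 1)
    fr <- runif(5, 0, 0.35)
    f <- freqTable(
      paralog = c("NOTCH2", "NOTCH2NLR", "NOTCH2NLC", "NOTCH2NLA",
                  "NOTCH2NLB"),
      frequency = fr)
    est <- locusAlleleCounts(f, total)
    if (!any(grepl("clamped", estimateFlags(est))))
      expect_equal(sum(alleleCounts(est)), total)
    expect_true(all(alleleCounts(est) >= 0))
  }
  # an overshooting direct estimate clamps the remainder and flags it
  over <- freqTable(
    paralog = c("NOTCH2", "NOTCH2NLR", "NOTCH2NLC", "NOTCH2NLA", "NOTCH2NLB"),
    frequency = c(0.5, 0.5, 0.4, 0.1, 0.1))
  estOver <- locusAlleleCounts(over, 6L)
  expect_true(any(grepl("clamped", estimateFlags(estOver))))
})

test_that("the NOTCH2>NOTCH2NLR conversion correction reassigns symmetric shifts", {
  mk <- function(n2, nlr) {
    counts <- c(NOTCH2 = n2, NOTCH2NLR = nlr, NOTCH2NLC = 2L,
                NOTCH2NLA = 2L, NOTCH2NLB = 2L)
    new("AlleleCountEstimate", counts = counts,
        totalInt = sum(counts), flags = character(0))
  }
  c31 <- n2nlrConversionCorrection(mk(3L, 1L))
  expect_equal(alleleCounts(c31)[["NOTCH2"]], 2L)
  expect_equal(alleleCounts(c31)[["NOTCH2NLR"]], 2L)
  expect_true(any(grepl("conversion corrected", estimateFlags(c31))))
  expect_equal(totalAlleles(c31), 10L)

  c22 <- n2nlrConversionCorrection(mk(2L, 2L))
  expect_equal(alleleCounts(c22)[["NOTCH2"]], 2L)
  expect_length(estimateFlags(c22), 0)

  c40 <- n2nlrConversionCorrection(mk(4L, 0L))
  expect_equal(unname(alleleCounts(c40)[c("NOTCH2", "NOTCH2NLR")]),
               c(2L, 2L))

  # asymmetric patterns are left alone
  c30 <- n2nlrConversionCorrection(mk(3L, 0L))
  expect_equal(alleleCounts(c30)[["NOTCH2"]], 3L)
})

test_that("genotyping recovers preset truths in >= 95% of replicates", {
  regions <- toyRegions()
  cat <- toyCatalog(regions)
  reps <- 40
  for (nm in c("modern_human_standard", "neanderthal_altai_like",
               "denisova3_like")) {
    hits <- 0
    for (r in seq_len(reps)) {
      cfg <- preset(nm, baseDepth = 30, seed = 7000L + r, regions = regions)
      ind <- simulateIndividual(cfg, catalog = cat)
      rep_ <- suppressWarnings(runPipeline(
        ind$depth, ind$pileups,
        config = pipelineConfig(regions = regions, catalog = cat)))
      truth <- locusAlleles(cfg)
      ok <- identical(unname(alleleCounts(rep_$alleleCounts)[names(truth)]),
                      unname(as.integer(truth)))
      if (ok) hits <- hits + 1
    }
    expect_gte(hits / reps, 0.95)
  }
})

test_that("dropping any single SUN leaves modal counts unchanged", {
  regions <- toyRegions()
  cat <- toyCatalog(regions)
  cfg <- preset("modern_human_standard", seed = 123L, regions = regions)
  ind <- simulateIndividual(cfg, catalog = cat)
  freqs <- sunFrequencies(ind$pileups, cat)
  ref <- alleleCounts(locusAlleleCounts(freqs, 10L))
  for (i in seq_len(nrow(freqs))) {
    est <- alleleCounts(locusAlleleCounts(freqs[-i, ], 10L))
    expect_equal(est, ref)
  }
})
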