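# Synthetic genome generator: determinism, calibration, presets, cohorts.

test_that("simulation is reproducible under the seed", {
  regions <- toyRegions()
  cat <- toyCatalog(regions)
  cfg <- preset("modern_human_standard", seed = 99L, regions = regions)
  a <- simulateIndividual(cfg, catalog = cat)
  b <- simulateIndividual(cfg, catalog = cat)
  expect_identical(depthValues(a$depth), depthValues(b$depth))
  expect_identical(a$pileups, b$pileups)
  # a different seed changes the draws
  cfg2 <- preset("modern_human_standard", seed = 100L, regions = regions)
  c <- simulateIndividual(cfg2, catalog = cat)
  expect_false(identical(a$pileups$dp, c$pileups$dp))
})

test_that("depth means follow the local allele count", {
  regions <- toyRegions()
  # only the parent present: multicopy lambda equals the base depth
  cfg0 <- genomeConfig(locusAlleles = c(NOTCH2 = 2L, NOTCH2NLR = 0L,
                                        NOTCH2NLC = 0L, NOTCH2NLA = 0L,
                                        NOTCH2NLB = 0L),
                       baseDepth = 30, seed = 4L, regions = regions)
  tr0 <- simulateDepth(cfg0)
  mm <- meanDepth(tr0, regionSet(regions$multiCopy))
  expect_lt(abs(mm - 30), 3 * sqrt(30 / 10000))

  # modal preset: multicopy/single ratio ~ 5 within 3 SE
  cfg <- preset("modern_human_standard", seed = 5L, regions = regions)
  tr <- simulateDepth(cfg)
  sm <- meanDepth(tr, regionSet(regions$singleCopy))
  mm <- meanDepth(tr, regionSet(regions$multiCopy))
  seRatio <- 5 * sqrt(1 / (150 * 10000) + 1 / (30 * 10000))
  expect_lt(abs(mm / sm - 5), 3 * seRatio)
})

test_that("allele depths are binomial in the carrying fraction", {
  regions <- toyRegions()
  cat <- toyCatalog(regions)
  cfg <- preset("modern_human_standard", seed = 6L, regions = regions)
  pil <- simulatePileups(cfg, cat)
  freqs <- sunFrequencies(pil, cat)
  nlc <- freqs[freqs$paralog == "NOTCH2NLC", ]
  # mean ad/dp over the NLC SUNs ~ 2/10 within 3 SE
  p <- 0.2
  se <- sqrt(p * (1 - p) / mean(nlc$dp)) / sqrt(nrow(nlc))
  expect_lt(abs(mean(nlc$frequency) - p), 3 * se)
  # empirical variance of ad/dp matches binomial theory to first order
  theo <- p * (1 - p) * mean(1 / nlc$dp)
  allf <- freqs[freqs$paralog %in% c("NOTCH2", "NOTCH2NLR", "NOTCH2NLC"), ]
  emp <- var(allf$frequency)
  theoAll <- p * (1 - p) * mean(1 / allf$dp)
  expect_gt(emp / theoAll, 0.5)
  expect_lt(emp / theoAll, 2.0)

  # a zero-allele locus has zero alternate depth at all of its SUNs
  cfgD <- preset("denisova3_like", seed = 7L, regions = regions)
  pilD <- simulatePileups(cfgD, cat)
  fD <- sunFrequencies(pilD, cat)
  expect_true(all(fD$adAlt[fD$paralog == "NOTCH2NLR"] == 0))
})

test_that("conversion tracts move SUN carriage inside their bounds", {
  regions <- toyRegions()
  cat <- toyCatalog(regions)
  st <- sunTable(cat)
  nlr <- st[st$paralog == "NOTCH2NLR", ]
  s <- nlr$position[5]; e <- nlr$position[15]
  cfg <- genomeConfig(
    conversionTracts = data.frame(donor = "NOTCH2", acceptor = "NOTCH2NLR",
                                  start = s, end = e, nAlleles = 2L,
                                  stringsAsFactors = FALSE),
    baseDepth = 60, seed = 8L, regions = regions)
  pil <- simulatePileups(cfg, cat)
  f <- sunFrequencies(pil, cat)
  fn <- f[f$paralog == "NOTCH2NLR", ]
  inside <- fn$position >= s & fn$position <= e
  expect_true(all(fn$frequency[inside] == 0))
  expect_lt(abs(mean(fn$frequency[!inside]) - 0.2), 0.05)
  # the donor gains carriage inside the tract
  fd <- f[f$paralog == "NOTCH2", ]
  insideD <- fd$position >= s & fd$position <= e
  expect_gt(mean(fd$frequency[insideD]), mean(fd$frequency[!insideD]))
})

test_that("presets encode the published configurations", {
  expect_equal(totalAlleles(preset("modern_human_standard")), 10L)
  expect_equal(totalAlleles(preset("neanderthal_altai_like")), 11L)
  den <- preset("denisova3_like")
  expect_equal(totalAlleles(den), 8L)
  expect_equal(locusAlleles(den)[["NOTCH2NLR"]], 0L)
  expect_equal(sum(locusAlleles(den)[c("NOTCH2NLR", "NOTCH2NLC",
                                       "NOTCH2NLA", "NOTCH2NLB")]), 6L)
  pv <- den@pointVariants
  expect_equal(pv$nAlleles[pv$name == "Exon1C"], 6L)
  expect_error(preset("nope"), "modern_human_standard")
})

test_that("cohorts derive per-individual seeds deterministically", {
  regions <- toyRegions()
  cat <- toyCatalog(regions)
  co1 <- simulateCohort(4, seed = 42L, regions = regions, catalog = cat)
  co2 <- simulateCohort(4, seed = 42L, regions = regions, catalog = cat)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$individuals$sample002$pileups,
                   co2$individuals$sample002$pileups)

  # n = 1 reproduces the preset simulated at the derived seed
  one <- simulateCohort(1, seed = 7L, regions = regions, catalog = cat)
  direct <- simulateIndividual(
    preset("modern_human_standard", seed = sunCN:::deriveSeed(7L, 1L),
           regions = regions), catalog = cat)
  expect_identical(one$individuals$sample001$pileups, direct$pileups)

  # truth table writing round-trips through TSV
  path <- tempfile(fileext = ".tsv")
  writeTruthTable(co1, path)
  back <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(back$total, co1$truth$total)
})

test_that("cohort variant frequencies set the expected mean carrier count", {
  regions <- toyRegions()
  cat <- toyCatalog(regions)
  co <- simulateCohort(60, variantFreqs = c(Exon1A = 0.75), seed = 3L,
                       regions = regions, catalog = cat)
  vp <- defaultVariantPositions(regions)
  counts <- vapply(co$individuals, function(ind) {
    row <- ind$truth@pointVariants
    row$nAlleles[row$name == "Exon1A"]
  }, numeric(1))
  # Binomial(4, 0.75): mean carrier count ~ 3 of 4
  se <- sqrt(4 * 0.75 * 0.25 / 60)
  expect_lt(abs(mean(counts) - 3), 3 * se)
})

test_that("emitted files are parsed by the package's own readers", {
  regions <- toyRegions()
  cat <- toyCatalog(regions)
  ind <- simulateIndividual(preset("modern_human_standard", seed = 12L,
                                   regions = regions), catalog = cat)
  bg <- tempfile(fileext = ".bedgraph")
  writeBedgraph(ind$depth, bg)
  back <- parseBedgraph(bg)
  expect_identical(depthValues(back), depthValues(ind$depth))
  expect_equal(back@start, ind$depth@start)

  pt <- tempfile(fileext = ".tsv")
  writePileupTable(ind$pileups, pt)
  backP <- parsePileupTable(pt)
  expect_equal(backP, ind$pileups)
})
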