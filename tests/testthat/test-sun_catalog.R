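# SUN derivation from locus sequences and BED round-trips.

test_that("identical paralogs yield an empty catalog", {
  parent <- "ACGTACGTAC"
  cat <- deriveSuns(parent, c(P1 = parent, P2 = parent), anchorStart = 101)
  expect_s4_class(cat, "SunCatalog")
  expect_length(cat, 0)
})

test_that("a variant unique to one paralog becomes a SUN in parent coordinates", {
  parent <- "ACGTACGTAC"
  p1 <- "ACTTACGTAC" # substitution at parent offset 2 (position 103)
  cat <- deriveSuns(parent, c(P1 = p1, P2 = parent), anchorStart = 101)
  tab <- sunTable(cat)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$position, 103)
  expect_equal(tab$paralog, "P1")
  expect_equal(tab$parentBase, "G")
  expect_equal(tab$sunBase, "T")
  expect_equal(tab$kind, "SNV")

  # same variant in both paralogs: not unique, excluded
  shared <- deriveSuns(parent, c(P1 = p1, P2 = p1), anchorStart = 101)
  expect_length(shared, 0)

  # two different alternates at one position are both SUNs
  p2 <- "ACATACGTAC"
  both <- deriveSuns(parent, c(P1 = p1, P2 = p2), anchorStart = 101)
  expect_equal(nrow(sunTable(both)), 2)
  expect_setequal(sunTable(both)$sunBase, c("T", "A"))
})

test_that("derived SUNs match a brute-force column scan on planted variant sets", {
  # oracle: paralogs are the parent with planted substitutions, so the true
  # multiple alignment is the identity and a per-column scan of the plant
  # list gives the expected records
  set.seed(42)
  for (rep in 1:8) {
    n <- 600
    parent <- randomSeq(n)
    pc <- strsplit(parent, "")[[1]]
    anchor <- 5001L
    positions <- sort(sample(10:(n - 10), 9))
    alt <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
    p1c <- pc; p2c <- pc; p3c <- pc
    expected <- data.frame(position = integer(0), paralog = character(0),
                           sunBase = character(0))
    for (k in seq_along(positions)) {
      i <- positions[k]
      b <- alt(pc[i])
      kind <- k %% 3
      if (kind == 0) {        # unique to P1
        p1c[i] <- b
        expected <- rbind(expected, data.frame(
          position = anchor + i - 1L, paralog = "P1", sunBase = b))
      } else if (kind == 1) { # unique to P2
        p2c[i] <- b
        expected <- rbind(expected, data.frame(
          position = anchor + i - 1L, paralog = "P2", sunBase = b))
      } else {                # shared by P1 and P3: excluded
        p1c[i] <- b; p3c[i] <- b
      }
    }
    cat <- deriveSuns(parent,
                      c(P1 = paste(p1c, collapse = ""),
                        P2 = paste(p2c, collapse = ""),
                        P3 = paste(p3c, collapse = "")),
                      anchorStart = anchor)
    got <- sunTable(cat)
    expected <- expected[order(expected$position, expected$paralog), ]
    expect_equal(got$position, expected$position)
    expect_equal(got$paralog, expected$paralog)
    expect_equal(got$sunBase, expected$sunBase)
    expect_true(all(got$kind == "SNV"))
  }
})

test_that("indels are left-aligned at the first changed parent base", {
  # parent has a homopolymer run; deleting any one of the A's is the same
  # event and must be reported at the first A of the run
  parent <- "CCGTAAAAGTCC"
  p1 <- "CCGTAAAGTCC" # one A of the run deleted
  cat <- deriveSuns(parent, c(P1 = p1, P2 = parent), anchorStart = 1)
  tab <- sunTable(cat)
  expect_equal(tab$kind, "deletion")
  expect_equal(tab$position, 5) # first A of the run
  expect_equal(tab$parentBase, "A")
  expect_equal(tab$sunBase, "-")

  ins <- "CCGTAAAAAGTCC" # one extra A
  cat2 <- deriveSuns(parent, c(P1 = ins, P2 = parent), anchorStart = 1)
  tab2 <- sunTable(cat2)
  expect_equal(tab2$kind, "insertion")
  expect_equal(tab2$position, 4) # anchored before the run after left shift
  expect_equal(tab2$sunBase, "A")
})

test_that("derivation rejects empty and unalignable input", {
  expect_error(deriveSuns("", c(P1 = "ACGT")), "no sequences")
  expect_error(deriveSuns("ACGT", character(0)), "no sequences")
  set.seed(7)
  expect_error(
    deriveSuns(randomSeq(300), c(Pbad = randomSeq(300))),
    "Pbad")
})

test_that("region filtering keeps in-window records and rejects inverted regions", {
  df <- data.frame(position = c(10L, 50L, 90L),
                   paralog = c("P1", "P1", "P2"),
                   parentBase = "A", sunBase = "G", kind = "SNV",
                   stringsAsFactors = FALSE)
  cat <- sunCN:::.newSunCatalog(df, "parent", c("P1", "P2"), c(1L, 100L))
  whole <- filterSunsByRegion(cat, 1, 100)
  expect_equal(sunTable(whole), sunTable(cat))
  mid <- filterSunsByRegion(cat, 40, 60)
  expect_equal(sunTable(mid)$position, 50L)
  none <- filterSunsByRegion(cat, 95, 99)
  expect_length(none, 0)
  expect_error(filterSunsByRegion(cat, 60, 40), "inverted")
})

test_that("SUN BED round-trip is bijective with 0-based half-open coordinates", {
  df <- data.frame(position = 103L, paralog = "P1", parentBase = "C",
                   sunBase = "T", kind = "SNV", stringsAsFactors = FALSE)
  cat <- sunCN:::.newSunCatalog(df, "parent", "P1", c(1L, 200L))
  bed <- writeSunBed(cat)
  expect_match(bed, "\t102\t103\t", fixed = TRUE)

  # empty catalog round-trips to an empty catalog
  empty <- sunCN:::.newSunCatalog(df[0, ], "parent", "P1", c(1L, 200L))
  expect_length(readSunBed(writeSunBed(empty), "parent", "P1"), 0)

  # 100 random records survive the round trip intact
  set.seed(11)
  pos <- sort(sample(1000:9999, 100))
  bases <- c("A", "C", "G", "T")
  pb <- sample(bases, 100, replace = TRUE)
  sb <- vapply(pb, function(b) sample(setdiff(bases, b), 1), character(1))
  rdf <- data.frame(position = pos,
                    paralog = sample(c("NOTCH2NLA", "NOTCH2NLB"), 100,
                                     replace = TRUE),
                    parentBase = pb, sunBase = unname(sb),
                    kind = sample(c("SNV", "deletion", "insertion"), 100,
                                  replace = TRUE),
                    stringsAsFactors = FALSE)
  rdf$sunBase[rdf$kind == "deletion"] <- "-"
  rdf$parentBase[rdf$kind == "insertion"] <- "-"
  # drop records duplicated on the identity key
  key <- paste(rdf$position, rdf$sunBase, rdf$kind, rdf$parentBase)
  rdf <- rdf[!duplicated(rdf$position), ]
  rcat <- sunCN:::.newSunCatalog(rdf, "parent",
                                 c("NOTCH2NLA", "NOTCH2NLB"),
                                 c(1L, 10000L))
  back <- readSunBed(writeSunBed(rcat), "parent",
                     c("NOTCH2NLA", "NOTCH2NLB"), sunRegion = c(1L, 10000L))
  expect_equal(sunTable(back), sunTable(rcat))

  expect_error(readSunBed(c("chr1\t10\t11\tP1|A|G|SNV", "chr1\t12"),
                          "parent"), "line 2")
  expect_error(readSunBed("chr1\t10\t11\tbadname", "parent"), "line 1")
})

test_that("no two SUNs from different paralogs share a position and alternate", {
  # catalog validity enforces the uniqueness invariant
  df <- data.frame(position = c(10L, 10L), paralog = c("P1", "P2"),
                   parentBase = "A", sunBase = "G", kind = "SNV",
                   stringsAsFactors = FALSE)
  expect_error(sunCN:::.newSunCatalog(df, "parent", c("P1", "P2"),
                                      c(1L, 100L)),
               "one paralog")
})
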