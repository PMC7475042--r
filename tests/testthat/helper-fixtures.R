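# Shared fixtures, built in code.

# compact layout for fast simulations (10 kb regions)
toyRegions <- function(width = 10000L) compactRegions(width)

toyCatalog <- function(regions = toyRegions()) {
  syntheticSunCatalog(regions = regions)
}

# allele-count vector summing to a given family total, NOTCH2 fixed at 2
allelesForTotal <- function(total) {
  stopifnot(total >= 6, total <= 14)
  base <- c(NOTCH2 = 2L, NOTCH2NLR = 2L, NOTCH2NLC = 2L,
            NOTCH2NLA = 2L, NOTCH2NLB = 2L)
  extra <- total - 10L
  if (extra >= 0) base["NOTCH2NLA"] <- base["NOTCH2NLA"] + extra
  else {
    take <- min(2L, -extra)
    base["NOTCH2NLR"] <- base["NOTCH2NLR"] - take
    if (-extra > 2L) base["NOTCH2NLC"] <- base["NOTCH2NLC"] - (-extra - 2L)
  }
  base
}

# hand-built frequency table for one sample
freqTable <- function(paralog, frequency, position = seq_along(paralog)) {
  data.frame(position = position, paralog = paralog,
             sunBase = rep("T", length(paralog)),
             dp = rep(100L, length(paralog)),
             adAlt = as.integer(round(frequency * 100)),
             frequency = frequency, stringsAsFactors = FALSE)
}

# random parent sequence
randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
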