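# Shared numeric helpers.

# Round half away from zero (commercial rounding). base::round() rounds
# half to even, which would bias allele counts at .5 boundaries.
roundHalfAway <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Apportion `total` integer units between parties proportionally to
# `shares`, using largest-remainder rounding so the parts sum to `total`
# exactly. Ties broken towards the earlier party. Zero shares all around
# split as evenly as possible.
largestRemainder <- function(shares, total) {
  stopifnot(total >= 0, all(shares >= 0))
  n <- length(shares)
  if (total == 0) return(setNames(rep(0L, n), names(shares)))
  if (sum(shares) == 0) shares <- rep(1, n)
  quota <- total * shares / sum(shares)
  base <- floor(quota)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    ord <- order(quota - base, shares, -seq_len(n), decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  setNames(as.integer(base), names(shares))
}

# Deterministic sub-seed derivation: keeps derived seeds positive and
# below 2^31 so they remain valid R integer seeds.
deriveSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream)) %% 2147483629)
}

# positions covered by 1-based inclusive intervals given as a 2-column
# matrix/data.frame (start, end); returns a sorted unique integer vector.
intervalPositions <- function(intervals) {
  if (is.null(intervals) || NROW(intervals) == 0) return(integer(0))
  intervals <- as.matrix(intervals)
  out <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    seq.int(intervals[i, 1], intervals[i, 2])
  }))
  sort(unique(as.integer(out)))
}
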