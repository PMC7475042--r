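# Population-level statistics: expected allele-count distributions under
# a two-locus polygenic (AABB x AABB) inheritance model, Kruskal-Wallis
# with Dunn's post hoc, two-sample Kolmogorov-Smirnov, Holm adjustment.

#' Expected allele-count sample under the polygenic model
#'
#' Two unlinked biallelic loci each segregating two variant alleles give
#' the 1:4:6:4:1 distribution over 0-4 alleles. Each draw picks a
#' category with the given probabilities and adds Gaussian jitter to
#' emulate sampling variation. The cohort-scale defaults are n = 2790
#' individuals with jitter sd 0.34.
#'
#' @param n Sample size.
#' @param support Category values.
#' @param probs Category probabilities (must sum to 1).
#' @param jitterSd Gaussian jitter standard deviation (same units as
#'   `support`).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- expectedPolygenicSample(n = 100, jitterSd = 0, seed = 1)
#' table(x)
#' @export
expectedPolygenicSample <- function(n = 2790, support = 0:4,
                                    probs = c(1, 4, 6, 4, 1) / 16,
                                    jitterSd = 0.34, seed = 1) {
  if (length(probs) != length(support) || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-12)
    stop("invalid probabilities: must be >= 0 and sum to 1")
  stopifnot(n >= 1, jitterSd >= 0)
  set.seed(as.integer(seed))
  cats <- sample(support, n, replace = TRUE, prob = probs)
  cats + rnorm(n, mean = 0, sd = jitterSd)
}

#' Expected allele-frequency sample at exome-cohort scale
#'
#' As [expectedPolygenicSample()] but on the frequency scale (support
#' 0-0.4 in steps of 0.1, jitter sd 0.034, n = 50000), with the support
#' rescaled before jittering to account for population-level loss of
#' NOTCH2NLC and NOTCH2NLR alleles: lost alleles shrink the
#' paralogous-position depth denominator, inflating every observed
#' frequency by `10 / (10 - 2 * (lossNLC + lossNLR))`.
#'
#' @param n Sample size.
#' @param support Frequency categories.
#' @param jitterSd Gaussian jitter standard deviation.
#' @param lossNLC,lossNLR Population loss rates in `[0, 1]`: the expected
#'   fraction of NOTCH2NLC (resp. NOTCH2NLR) alleles absent per
#'   individual, as estimated from a genotyped cohort.
#' @param probs Category probabilities.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
expectedUkbSample <- function(n = 50000, support = seq(0, 0.4, by = 0.1),
                              jitterSd = 0.034, lossNLC = 0, lossNLR = 0,
                              probs = c(1, 4, 6, 4, 1) / 16, seed = 1) {
  stopifnot(lossNLC >= 0, lossNLC <= 1, lossNLR >= 0, lossNLR <= 1)
  adj <- 10 / (10 - 2 * (lossNLC + lossNLR))
  expectedPolygenicSample(n = n, support = support * adj, probs = probs,
                          jitterSd = jitterSd, seed = seed)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square p value on k - 1 degrees
#' of freedom. Fully tied data (every value identical) are defined to
#' give H = 0, p = 1 rather than a divide-by-zero.
#'
#' @param groups List of >= 2 numeric samples.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups")
  stopifnot(all(vapply(groups, length, integer(1)) >= 1),
            sum(lengths(groups)) >= 3)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1)
    return(list(statistic = 0, df = length(groups) - 1L, p.value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Dunn's post hoc test with multiplicity adjustment
#'
#' Pairwise mean-rank comparisons on the pooled ranking:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` with
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`; two-sided normal p
#' values, Holm-adjusted by default. Degenerate fully tied data give
#' z = 0, p = 1.
#'
#' @param groups Named (or unnamed) list of >= 2 numeric samples.
#' @param method Multiplicity adjustment passed to [stats::p.adjust()].
#' @return data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p.value`, `p.adjusted`.
#' @export
dunnTest <- function(groups, method = "holm") {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  meanRanks <- tapply(r, g, mean)
  tie <- table(x)
  tieTerm <- sum(tie^3 - tie) / (12 * (N - 1))
  varBase <- N * (N + 1) / 12 - tieTerm
  pairs <- utils::combn(seq_along(groups), 2)
  zs <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se2 <- varBase * (1 / length(groups[[i]]) + 1 / length(groups[[j]]))
    if (se2 <= 0) 0 else
      unname((meanRanks[[i]] - meanRanks[[j]]) / sqrt(se2))
  }, numeric(1))
  out <- data.frame(group1 = nms[pairs[1, ]], group2 = nms[pairs[2, ]],
                    z = zs, p.value = 2 * pnorm(-abs(zs)),
                    stringsAsFactors = FALSE)
  out$p.adjusted <- p.adjust(out$p.value, method = method)
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic p value.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `statistic` (D) and `p.value`.
#' @export
ksTwoSample <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down Bonferroni with the running maximum, capped at 1: adjusted
#' p values are always at least the raw ones and order-preserving.
#'
#' @param p Vector of p values in `[0, 1]`.
#' @return Adjusted p values.
#' @examples
#' holmAdjust(c(0.01, 0.04))
#' @export
holmAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "holm")
}
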