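---
title: "Paralog-specific allele counting with singly unique nucleotides"
author: "sunCN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paralog-specific allele counting with singly unique nucleotides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The human-specific *NOTCH2NL* genes (*NOTCH2NLA*, *-B*, *-C* at 1q21.1 and
the pseudogene *NOTCH2NLR* at 1p12) arose by segmental duplication of the
5' part of *NOTCH2* and are nearly identical to their parent and to each
other. Standard variant callers and copy-number tools cannot place short
reads confidently within the family, and ongoing interlocus gene
conversion moves sequence -- including functionally critical Exon1
variants -- between the loci. `sunCN` implements a genotyping strategy
that embraces the ambiguity instead of fighting it:

1. **Masked-reference depth ratio.** With all *NOTCH2NL* loci masked in
   the reference, every family read piles onto the parent *NOTCH2* locus.
   The mean depth of that multicopy region, divided by the mean depth of
   a nearby single-copy region (which represents exactly two alleles),
   gives the combined family allele count:
   \[ \hat{t} = 2 \cdot \frac{\bar{d}_{\text{multi}}}{\bar{d}_{\text{single}}}. \]
2. **SUN frequencies.** A *singly unique nucleotide* (SUN) is a variant
   carried by exactly one paralog relative to the parent and all other
   paralogs. In the pooled pileup, the alternate-allele fraction
   `AD/DP` at a SUN estimates the carrying paralog's share of the
   family's alleles; averaged over a locus's SUNs and multiplied by
   \(\hat{t}\), it yields that locus's allele count.
3. **Subtraction and ratio split.** *NOTCH2NLA* and *NOTCH2NLB* are too
   recently diverged to have many SUNs and exchange sequence by gene
   conversion, so their counts are not estimated directly: the counts of
   *NOTCH2*, *NOTCH2NLR* and *NOTCH2NLC* are subtracted from the total
   and the remainder is split between A and B in the ratio of their mean
   SUN frequencies.
4. **Conversion correction.** Gene conversion of *NOTCH2NLR* toward
   *NOTCH2* sequence shows up as the symmetric pattern
   (NOTCH2 = 2 + k, NOTCH2NLR = 2 - k); the correction reassigns the k
   alleles back.

Downstream stages profile gene conversion along per-SUN allele-count
tracks, quantify the dosage of functional variants (the Exon1 high/low/
extra-low protein classes, archaic missense variants, the R113* and
exon-2 splice-acceptor loss-of-function variants) and test population
allele-count distributions against a polygenic expectation.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| single-copy region | chr1:119908310--119989035 | bp (1-based) | diploid reference depth |
| multicopy region | chr1:119990490--120087745 | bp | family pileup on the masked reference |
| SUN region | chr1:119990474--120087745 | bp | maximal duplicon shared by all loci |
| population filter threshold | 0.67 (strict `>`) | normalized frequency | drops ambiguous/population-specific sites |
| expected SUN fraction | 2/10 | frequency | default carrying alleles over modal total |
| rounding | half away from zero | -- | unbiased at `.5` boundaries |
| segmentation `minRun` | 3 SUNs | -- | minimum evidence for a conversion tract |
| segmentation `defaultCount` | 2 alleles | alleles | expected diploid carriage |

The published end coordinate of the SUN region is truncated in print; the
package defaults to the multicopy-region end (120087745) and makes the
region configurable everywhere.

The filter statement ">0.67 frequency in the population" does not specify
a normalization or a cohort summary. `sunCN` interprets it as a strict
threshold on the cohort **median** of observed frequency divided by the
expected fraction (2 of the modal 10 alleles), with `stat = "mean"`
available. A SUN whose normalized frequency is 1.0 in every individual
is never removed; a common SNP suppressing the site in half the cohort
drives the median to ~0.5 and is excluded.

## The A/B split and rounding

Counts are reported as integers. Products `frequency x total` are rounded
half away from zero (`round()`'s banker's rounding would bias counts at
`.5`). The A/B remainder split uses largest-remainder rounding so that
the five locus counts always sum to the coverage total: conservation is
an invariant, not a hope. When the directly estimated loci overshoot the
total (possible on noisy data), the remainder clamps at zero and the
estimate carries an explicit flag instead of failing.

## Gene-conversion segmentation

The published analysis reads conversion tracts off median SUN-track
figures by eye; no quantitative rule is given. The package's rule is
deliberately simple and exposed in the configuration: a maximal run of at
least `minRun = 3` consecutive SUNs whose rounded allele count deviates
from the default (2) in the same direction is one segment, with magnitude
equal to the median rounded deviation. Per-sample tracks at 30x are noisy
(s.d. of a single-site count is ~0.37 alleles at the modal
configuration), so single-allele tracts are reliably detected only on
cohort **median** tracks; full losses (frequency exactly 0) are reliable
per sample. The B-paralog complement track is inferred as
`pairTotal - A`, clamped at zero, mirroring the published
`Exon1B = 4 - Exon1A` rule.

## The synthetic cohort generator

The generator emulates exactly the statistical structure the estimators
consume, not the sequencing process: per-position depth is
`Poisson(baseDepth x localAlleles / 2)` and the variant-supporting depth
at each SUN or variant site is `Binomial(DP, carrying / total)`.
Conversion tracts move SUN carriage between donor and acceptor inside
their bounds; point variants carry their configured allele counts.
Presets encode the three study configurations: the modal human genome
(ten alleles, two per locus, Exon1 classes A/B/C at 2/2/2), an
Altai-Neanderthal-like genome (eleven alleles with an extra A/B-pair
allele, whole-region NOTCH2-to-NOTCH2NLR conversion on one allele, M40I
on one allele, N232S on two) and a Denisova3-like genome (homozygous
NOTCH2NLR deletion, six NOTCH2NL alleles all carrying the Exon1 C
variant, E258A on two alleles).

What the generator does **not** model: sequencing error, ancient-DNA
damage, GC bias, mappability structure, or depth heterogeneity of real
ancient libraries -- the published pipeline consumes quality-filtered
pileups, and none of the estimators act on base qualities. Passing
recovery tests therefore demonstrates correctness of the estimators under
their own statistical model, not robustness to artefacts of real data.

All randomness derives from one integer seed through a deterministic
sub-seed scheme (`(seed * 48271 + stream) mod 2147483629`), so depth
tracks, pileups and whole cohorts are bit-for-bit reproducible; derived
seeds stay below 2^31.

## Variant positions and coordinate conventions

Internal coordinates are 1-based inclusive throughout; BED and bedGraph
are 0-based half-open and convert at I/O. The generator places its
functional-variant marker sites at fixed fractions of the multicopy
region so compact test genomes (10 kb regions) keep the same layout as
the full-scale coordinates; where a parent-locus projection of a variant
is not published, the marker position is a synthetic placeholder -- the
estimators only use the site's `AD/DP`, never its coordinate. The three
published hg38 paralogous-position tables (Exon1 A-variant, exon-2
splice-acceptor, N232S) are shipped verbatim in
`builtinPositionTables()`; the N232S allele is absent from the reference,
so its `variantLocus` attribution (NOTCH2NLB) is a configurable
convention.

## Expected population distributions

The two-locus polygenic expectation (AABB x AABB) gives categories
0--4 with probabilities 1:4:6:4:1 /16. Samples are generated by drawing
the category and adding Gaussian jitter (sd 0.34 at cohort scale
n = 2790; sd 0.034 on the frequency scale at exome scale n = 50000) --
equivalent to the stated mixture-of-normals and reproducible under a
seed. The exome-scale expectation is "adjusted for loss of NOTCH2NLC and
NOTCH2NLR"; the mechanism is unstated in the source analysis, so the
package applies a deterministic support rescaling by
`10 / (10 - 2 (lossNLC + lossNLR))`: lost alleles shrink the
paralogous-position depth denominator, inflating each observed
frequency proportionally. The loss rates are caller-supplied cohort
estimates.

Rank statistics are delegated to R's own implementations
(`kruskal.test`, `ks.test`, `p.adjust`); Dunn's test is implemented from
the mean-rank formula with tie correction, since no post-hoc package is
a dependency. Fully tied data define H = 0, p = 1 (degenerate-input
safety). Dunn p values are two-sided.

## Numerical choices and degenerate inputs

- Zero-depth pileup sites are *missing*, never frequency 0 -- a deleted
  locus (frequency exactly 0 at positive depth) must stay
  distinguishable from absent data.
- `meanDepth` errors on a region fully removed by the repeat mask;
  `totalAlleleCount` errors on non-positive single-copy coverage.
- A single-sample "cohort" passes the population filter entirely, with a
  warning, because a cohort summary is undefined.
- Parsers report the offending line number for malformed rows.

## Problem sizes

Property and recovery tests run on 10 kb compact regions (the recovery
guarantees hold for regions of at least 10 kb at 30x), with 40--100
seeded replicates per claim; end-to-end checks of the preset
configurations use the full-scale coordinates (~180 kb simulated per
individual, three seeds per preset). The full suite completes in well
under a minute per module on one CPU.

## Known limitations

- Single-site quantities (the Exon1 class counts, archaic variant
  dosages) carry binomial noise of ~0.3 alleles at 30x; at that depth a
  rounded single-site count matches truth ~87% of the time. Cohort
  medians, or deeper data, are needed for stable single-site calls.
- The Denisovan E258A worked value (38 of 203 reads called as two
  alleles) is not reproducible under `round(AD/DP x total)` for any
  obvious total (6 or 8 gives 1.1--1.5); the estimator implements the
  general rule and that example is not used as a reference point.
- The A/B split assumes the pair's SUN frequencies are proportional to
  their allele counts; a conversion tract covering *all* of a paralog's
  few SUNs would bias the split, which is why tracks and segments are
  reported alongside the counts.
- No GC or mappability correction is applied, matching the source
  analysis.
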