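---
title: "Methods: discovering cancer-associated microsatellite loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering cancer-associated microsatellite loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Microsatellites (MSTs) are tandem repeats of 1–6 nt motifs, typically
10–15 nt long, whose tract length is polymorphic across individuals. At a
given locus a diploid sample carries a pair of tract lengths — here called
its *genotype*, written `a/b` with `a <= b`. A *cancer-associated
microsatellite locus* (CAML) is a locus at which the genotype distribution
differs between a cancer cohort and a control cohort. `camlscan` implements
the full discovery-and-classification pipeline: repeat catalog construction,
read-level genotyping, case/control association with multiple-testing
control, signature-based sample classification, and regulatory/driver
annotation, plus a seeded synthetic-cohort generator that stands in for the
controlled-access exome data such studies use.

## Catalog construction

`detect_repeats()` finds maximal perfect tandem runs of each unit size 1–6
and collapses composite calls to the smallest period (only primitive motifs
are reported; by the Fine–Wilf periodicity argument a run of two or more
full units cannot carry two distinct primitive periods, so this rule is
exact). Candidate tracts shorter than `min_length = 10` nt are not reported:
shorter runs are ubiquitous homopolymer noise and below the length the
pipeline ever uses.

`apply_catalog_filters()` applies the selection rules:

* **Length by region**: tract `>= 12` nt, relaxed to `>= 10` nt inside exons
  (exon annotation from a BED of exons with gene symbols; loci inside a
  gene's exon span but not an exon are classed `intron`, others
  `intergenic`).
* **Flank uniqueness**: each locus stores 10-nt flanks (chosen so a 100-nt
  read can span tract plus anchors). The concatenated 20-nt context — with
  the tract elided — must occur exactly once, over both strands. Because the
  raw reference never contains that 20-mer contiguously (the tract sits in
  between), the probe is searched in the *tract-collapsed* reference, i.e.
  the reference with every detected repeat tract deleted: the locus' own
  context then contributes exactly one hit, and a context duplicated
  anywhere else yields two or more and the locus is removed. The collapse
  set is recomputed from the full reference inside the filter, which makes
  filtering idempotent. A palindromic context matches itself on both strands
  (count 2) and is excluded — a deterministic, conservative tie-break.
* **Proximity**: a pair of detected tracts separated by fewer than 5
  non-repeat bases cannot be genotyped independently by short flank anchors;
  both members are excluded. The exclusion is evaluated against the full
  detected candidate set, not against post-filter survivors. The source
  description of this rule is ambiguous about which distance is anchored
  where; this reading (inter-tract gap < 5, which also implies the 200-base
  window condition) is the one implemented and tested.
* **Impurity option**: `max_impurity_frac` merges in-phase same-motif runs
  across mismatching gaps while the mismatches stay within
  `floor(frac * tract_length)`. The default is 0 (pure repeats only): the
  pipeline's statistics operate on tract lengths, for which pure repeats
  suffice, and an alignment-based impure-repeat model is out of scope.

## Genotyping from reads

Mapping position is trusted only to shortlist reads near a locus. A read
contributes an observation iff it contains an exact match of the inner 5 nt
of both reference flanks — i.e. it spans the whole tract plus at least five
anchoring bases per side — and the tract between the matched anchors is the
observed allele. Substitutions inside the tract change the binned repeat
sequence but not its length, so tract SNPs do not split the length spectrum.
When a 5-mer anchor recurs by chance within a read, the anchor pair whose
implied tract best matches a periodic extension of the locus motif is used
(ties to the leftmost pair); reads failing validation are simply dropped.
One mismatch per anchor window can be allowed (`max_flank_mismatch = 1`)
but exact matching is the default, matching the validation intent.

`call_genotype()` aggregates observations by allele length and retains
lengths supported by at least `min_allele_fraction = 0.2` of the validated
depth. This rule is the package's own choice — the source procedure never
states how two alleles are selected from a noisy bin spectrum — and is the
standard stutter-suppression device in STR callers: a PCR stutter bin one
unit off rarely reaches 20% of depth, while a true heterozygous allele at
balanced sampling rarely falls below it (at depth 15 the probability that a
true allele draws fewer than 3 of 15 reads is under 2%). One retained
allele is a homozygous call, two a heterozygous call, more than two marks
the locus `multi_allelic` and it is excluded; fewer than
`coverage_min = 15` validated reads (the 15x callability rule) gives
`low_coverage`. Raising `coverage_min` can only shrink the called set
(monotonicity, tested).

## Association and the signature

Samples with fewer than 15,000 called loci are excluded (uniformity of
coverage across heterogeneous sequencing runs; scaled down proportionally on
synthetic tables), and loci called in fewer than 10 samples of either cohort
are excluded.

At each surviving locus the *predominant genotype* is the modal genotype of
the called control samples; ties break toward the genotype homozygous for
the reference tract length, then toward the numerically smallest pair (the
source is silent; both tie-breaks are deterministic and tested). Every
other genotype observed at the locus is a hypothesis: its carriers versus
non-carriers among callable samples form a 2×2 table

|            | genotype g | not g |
|------------|-----------|-------|
| cases      | a         | b     |
| controls   | c         | d     |

tested with the exact two-sided Fisher test (sum of hypergeometric table
probabilities no larger than the observed one, with the conventional
`1 + 1e-7` relative tie tolerance). The relative risk is
`RR = (a/(a+b)) / (c/(c+d))`; when `c = 0`, `RR` is reported as `Inf` with a
Haldane–Anscombe companion (+0.5 to each cell) for ranking. Testing
(locus, genotype) pairs — not loci — is deliberate: signatures consist of
variant allelic pairs, and the two-stage counts reported in such studies
(significant genotypes, then FDR-corrected signature) only make sense at
genotype resolution.

The signature is assembled in two stages: hypotheses with raw `p <= 0.01`
are candidates, and the Benjamini–Hochberg step-up procedure is applied over
*all* tested hypotheses at the data-driven level `q* = 1/X`, where `X`
counts tested hypotheses with `p` strictly below 1 — so fewer than one
signature member is expected to be a false discovery. Members must pass
both. Whether the original procedure applied BH before or after the 0.01
filter, and whether `X` counts loci or genotypes, cannot be determined from
its description; this package applies BH over all genotype hypotheses with
strict `p < 1` for `X`, and documents that choice here.

## Classification

For each sample, the *detection fraction* is the share of signature loci
callable in that sample whose called genotype equals the signature genotype.
"Detectable" means `status == "called"`, not merely covered. Samples with no
callable signature locus are unscorable and excluded from ROC analysis but
reported. The ROC evaluates every observed fraction as a cutoff
(`fraction >= t` predicts case) plus an all-negative extreme; the cutoff
maximizes Youden's `J = sensitivity + specificity − 1`, with ties broken
toward higher specificity (equivalently the higher cutoff). The original
study's ROC criterion sits in an unavailable supplement; Youden's J is the
standard optimum and is stated here precisely so results are reproducible —
cutoffs may therefore differ from the original percentages. Fractions are
not binned before thresholding; the histogram view (`detection_histogram()`)
is presentation only.

Grade-vs-grade comparisons (`cross_signature_comparison()`) run the same
scoring with one cancer cohort as positive and the other as negative.
`tumor_germline_concordance()` compares matched compartments per signature
locus: genotype agreement over pairs called in both, and a Fisher test of
signature-genotype carrier frequency between compartments, flagging loci at
`p < 0.01`.

## Annotation

Distances to CpG islands and TFBS are gap distances between intervals
(overlap or abutment → 0); the source does not define its convention, and
the gap convention is the one interval libraries agree on. Windows are
10 kb (CpG) and 40 bases (TFBS), measured from the tract edge. The driver
gene panel follows the printed list verbatim — including the apparent
misspellings `MSF6` and `MLH2` — with documented aliases `MSH6`/`PMS2`
available via `driver_gene_panel(aliases = TRUE)`. The driver/CAML crosstab
bins detection fractions at 20-percent steps against driver counts 0–5
(higher counts fold into 5), with per-row percentages.

## The synthetic world

The generator's defaults are the stated discovery scenario: 500 loci, 100
cases and 100 controls, 20 planted CAML genotypes with control carrier
frequency 0.2 and case carrier frequency 0.6 (relative risk 3), spanning
depth ~ Poisson(30) (within the 15–60x range the method expects), 100-nt
reads, and 2% per-sample/locus dropout. Null loci share a per-locus variant
frequency drawn from U(0.05, 0.3) in both cohorts, so unplanted loci are
exchangeable. Each locus' variant genotype is a one-unit heterozygous
expansion of the reference tract; alleles are drawn independently per locus
(the statistics treat loci independently — no linkage). Stutter is a
single ±1-unit slip per read at `stutter_rate`; that is sufficient to
exercise the allele-fraction rule without a full PCR model. Tract lengths
are 12–20 nt from a mono/di/tri-nucleotide motif set; spacers of ≥ 300
repeat-free bases separate loci, with junction windows rejected until no
tandem run of ≥ 8 nt spans them, so the truth catalog and a fresh detection
of the simulated reference agree exactly.

What the generator does **not** emulate: real human allele-frequency
spectra, exome capture bias, contamination, multi-step stutter, indel
alignment artifacts, or population structure. A green test therefore
establishes that the machinery is correct on data with the assumed
statistical structure — not that the pipeline's operating characteristics
transfer to real exomes.

All randomness flows from one seed; stages derive sub-seeds at fixed
offsets, so repeated runs are byte-identical.

## Numerical choices and edge cases

* Fisher p-values are enumerated exactly and clamped to [0, 1]; tied table
  probabilities are included under a `1 + 1e-7` relative tolerance, the
  convention of `stats::fisher.test`, so edge-case tables agree with the
  conventional value.
* `X = 0` (all p-values equal 1) yields an empty signature rather than a
  division by zero.
* An allele spectrum where no length reaches the allele fraction (many
  small bins) is treated as `multi_allelic` — the spectrum supports no
  two-allele call.
* Zero callable samples in a cohort produce an `NA` p-value sentinel and
  the hypothesis is excluded from the BH stage.
* Loci without full 10-nt flanks (sequence edge) are excluded with a
  warning rather than an error, so genome-edge artifacts do not abort runs.

## Scaling in the test suite

The acceptance suite runs the stated scales (all 2×2 tables with margins
≤ 60; 1,000 random p-vectors; 500 loci × 20 samples of reads; five
discovery seeds at 100 + 100 samples; twenty null seeds). The end-to-end
determinism check uses a smaller cohort (60 loci, 16 + 16 samples) with a
strong planted effect (carrier 0.1 vs 0.9) and noise switched on
(stutter 5%, base error 0.2%), because at that sample size the default
effect (0.2 vs 0.6) has no power against the strict `q* = 1/X` cutoff and
an empty signature would leave the classification stage unexercised; the
determinism property itself is scale-free.
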