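Package: camlscan
Title: Discovery of Cancer-Associated Microsatellite Loci from Case/Control Exome Cohorts
Version: 0.1.0
Authors@R:
    person("CAMLscan", "Developers", email = "camlscan@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering cancer-associated
    microsatellite loci (CAMLs) from case/control exome sequencing cohorts.
    Builds a filtered catalog of perfect tandem repeats with unique flanking
    context from a reference sequence, calls per-sample allele-length-pair
    genotypes from aligned reads using flank-anchored tract extraction with
    coverage gating, compares per-locus genotype distributions between cohorts
    with two-sided Fisher exact tests and a Benjamini-Hochberg signature
    cutoff, classifies samples by their fraction of detectable signature
    genotypes with ROC threshold selection, and annotates signature loci with
    regulatory-element proximity and driver-mutation co-occurrence. A fully
    seeded synthetic-cohort generator (reference, truth catalog, cohort
    genotypes, aligned reads) makes every stage testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
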