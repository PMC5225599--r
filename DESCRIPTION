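Package: bsm5c
Title: Transcriptome-Wide m5C Calling from RNA Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for calling 5-methylcytosine (m5C) candidate
    sites from RNA bisulfite sequencing pileups. Conversion error is
    estimated from unmethylated spike-in transcripts and each cytosine is
    tested with an exact one-sided binomial test followed by
    Benjamini-Hochberg FDR control, coverage and non-conversion-rate
    thresholds, and three-replicate consensus. Candidates predicted to be
    base-paired in the secondary structure of their transcript are
    discarded. Downstream analyses cover unique/common classification
    between sample types with a four-way decomposition of unique sites,
    meta-gene positional profiles with Fisher exact segment enrichment,
    permutation tests of overlap with miRNA target and RNA-binding-protein
    tracks, and IUPAC scanning for the m6A consensus motif. A fully
    seeded simulator generates a small annotated transcriptome with
    planted methylation, hairpins, spike-ins and feature tracks so every
    statistic can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
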