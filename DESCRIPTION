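Package: hapcohort
Title: Case-Control Haplotype Association Analysis for a Low-Frequency
    Regulatory Locus, with a Matched Synthetic Cohort Generator
Version: 0.1.0
Authors@R:
    person("Maintainer", "hapcohort", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for characterizing a low-frequency regulatory
    risk haplotype from targeted-sequencing case-control data: sample and
    variant quality control (call rate, depth, Hardy-Weinberg exact test in
    controls), genomic-control-corrected allelic association with
    Benjamini-Hochberg FDR, trans-ethnic Cochran-Mantel-Haenszel stratified
    tests and conditional analysis, EM haplotype-frequency estimation with
    pairwise linkage disequilibrium and D'-based tag selection, median-joining
    haplotype networks, diplotype dose-effect and cis-eQTL dosage regression,
    an internal-standards ("associative T") differential-expression procedure,
    and autoantigen-array fold-enrichment analysis.  A seeded synthetic cohort
    generator emulates the statistical structure these analyses assume (three
    ancestral haplotypes, stratum-specific frequencies, per-haplotype odds
    ratios, an additive cis-eQTL, reference-stable and differentially
    expressed genes, antigen-specific serology shifts) so the whole chain is
    testable without controlled-access data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
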