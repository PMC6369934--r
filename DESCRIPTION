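Package: afdscan
Title: Pool-Seq Allele Frequency Difference Scans for Parallel Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting and characterising parallel
    adaptation from pooled sequencing (Pool-seq) data. Implements genome-wide
    absolute allele frequency difference (AFD) scans integrated over
    population-pair comparison categories, detection of core SNPs in
    independent high-differentiation regions, basic/acidic allele polarity
    classification with exact binomial and permutation asymmetry tests
    against an ancestral (marine) proxy, synthetic diploid genotype and
    binary-similarity inputs for phylogenies and ordination, a windowed
    high-MAF SNP-density selective-sweep statistic, and major-axis
    regression concordance between ancestral sub-samples. A Wright-Fisher
    cohort simulator with selection on standing variation, sweep footprints
    on linked sites and pooled read sampling exercises every stage without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    ape,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
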