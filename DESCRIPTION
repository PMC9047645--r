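Package: pqtlmeta
Title: Meta-Analysis, Conditional Analysis and Mendelian Randomization for
    Protein QTL Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the post-cohort stages of a protein quantitative trait
    locus (pQTL) genome-wide association study: fixed-effect inverse-variance
    meta-analysis across cohorts with sex-stratified X-chromosome handling,
    exact leave-one-cohort-out meta-subtraction, linkage-disequilibrium (LD)
    statistics, LD scores and greedy p-value clumping from a genotype
    reference panel, approximate conditional and joint multi-SNP analysis for
    secondary-signal discovery, per-variant variance-explained and
    heritability-fraction accounting, two-sample Mendelian randomization
    (Wald ratio and inverse-variance weighting) with cis and genome-wide
    instrument selection, and an LD-score-corrected logistic regression for
    annotation enrichment of genome-wide significant signals. Includes a
    synthetic multi-cohort study generator with full ground truth (block-LD
    genotypes, a strong X-chromosome cis locus, autosomal trans loci, a
    downstream binary outcome, and enriched annotation tracks) so every stage
    can be validated against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
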