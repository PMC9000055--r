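Package: transmodR
Title: Trans-Modifier Association Analysis for ABCA4/Stargardt Disease
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-level qualifying-variant collapsing analysis against
    internal and ethnicity-matched external control cohorts, EM estimation
    of multi-SNP haplotype spectra from unphased genotypes, and
    genotype-stratified tag-SNP association testing, as used to search for
    trans-acting genetic modifiers of ABCA4/Stargardt disease in macular
    dystrophy genes. Includes a seeded synthetic-cohort generator emulating
    the discovery-study design, a replay mode that recomputes published-style
    summary statistics from bundled contingency tables, and exact plus
    asymptotic two-by-two association statistics (minimum-likelihood Fisher
    exact test, Pearson chi-square, Woolf odds-ratio confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Genetics, VariantAnnotation, SNP, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
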