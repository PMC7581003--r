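Package: felcohort
Title: Cohort Variant Analysis for Resequencing Studies of the Domestic Cat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort-scale variant analysis in feline (and other
    small-cohort mammalian) resequencing studies: KING-robust kinship
    estimation with iterative unrelated-set pruning, constraint-group
    (pLI-stratified) SNV density and singleton-fraction enrichment statistics
    with permutation confidence intervals and Fisher contrasts, minor allele
    frequency spectra, loss-of-function singleton candidate prioritization,
    dual-caller structural variant consensus merging with genomic region
    annotation, and segregation analysis of dominant disease variants
    (Hardy-Weinberg and recessive-lethal tests). Includes a synthetic-cohort
    generator that emits multi-sample VCFs, impact annotations, gene models,
    jittered dual-caller structural variant call sets and genotyping panels,
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
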