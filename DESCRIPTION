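Package: PairedTumorKit
Title: Integrated Paired Tumor-Normal Somatic Variant, Copy-Number and
    Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the integrated analysis of paired tumor/normal
    sequencing studies of genomically quiet pediatric tumors. Implements a
    permutation test on variant allele fractions for somatic single-nucleotide
    variant calling with VAF_frac volcano selection, VAF-based loss of
    heterozygosity and gene-level copy-number calling with a windowed
    Z-statistic for array probes, RPKM quantification with a negative binomial
    two-group differential expression test using asymmetric selection
    thresholds, hypergeometric gene-set over-representation with cancer-gene
    intersection ranking and reference-gene-relative subgroup scoring, and a
    seeded synthetic cohort generator with ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    VariantAnnotation,
    DESeq2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'PairedTumorKit-package.R'
    'cna.R'
    'enrichment.R'
    'expression.R'
    'generics.R'
    'io.R'
    'pipeline.R'
    'simdata.R'
    'somatic.R'
    'utils.R'
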