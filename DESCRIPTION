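Package: MRDassoc
Title: MRD-Stratified Genomic Association Analysis for ETV6::RUNX1 Leukemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for associating genomic features with measurable residual
    disease (MRD) response groups in ETV6::RUNX1 childhood B-cell acute
    lymphoblastic leukemia. Implements MRD response-group classification at
    mid-induction, end-of-induction and end-of-consolidation timepoints;
    copy-number variant filtering, multi-assay harmonization and a
    within-chromosome-arm randomization test yielding empirical p-values for
    locus-level CNV/response association; Fisher's exact mutation-prevalence
    testing and CRISPR-screen gene-set deletion-burden analysis; 96-context
    trinucleotide mutation catalog construction and non-negative least-squares
    signature exposure refitting with MRD correlation; CPM-normalized gene-set
    module scoring and copy-number dosage expression testing. A seeded
    synthetic-cohort generator emulates the statistical structure of such a
    cohort so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    pracma,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'MRDassoc-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'mutsig.R'
    'cohort.R'
    'stats-core.R'
    'cnv-assoc.R'
    'variant-assoc.R'
    'expression-scores.R'
    'synthetic-cohort.R'
    'io.R'
    'pipeline.R'
biocViews: CopyNumberVariation, SomaticMutation, GeneExpression,
    StatisticalMethod, Leukemia
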