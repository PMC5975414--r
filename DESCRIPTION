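Package: spliceusage
Title: Exon and Junction Usage Computation and Splicing Visualization for
    Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes splicing-index style exon/junction usage values from
    RSEM-type quantification matrices, annotates quantified features to
    transcript isoforms by genomic overlap against GTF gene models,
    harmonizes raw TCGA-style clinical attributes into categorical grouping
    variables with overall-survival (time, event) construction, estimates
    Kaplan-Meier curves for cohorts split by an isoform-expression cutoff,
    and renders multi-track usage plots, per-group isoform box plots and
    Kaplan-Meier plots as deterministic static SVG. Ships a seeded synthetic
    cohort generator (gene models, quantifications, clinical tables with a
    ground-truth manifest) so the full workflow is testable without any
    data download, and a command-line interface wiring the steps together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
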