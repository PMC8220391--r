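Package: prismalink
Title: Peptide-Array (PRISMA) and BioID Interactome Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end analysis of peptide-array interaction screens
    (PRISMA) and BioID proximity-labeling experiments for intrinsically
    disordered proteins. Designs tiling peptide arrays with PTM variants,
    parses and filters MaxQuant-style protein-group LFQ tables, imputes
    missing values from a downshifted normal distribution, tests
    differential enrichment with empirical-Bayes moderated t-statistics
    against peptide-specific control groups, calls BioID interactors with
    a dual negative-control rule, and integrates both interactomes with
    isoform-preference scoring and score-thresholded network filtering.
    Includes a synthetic label-free-quantification data generator with
    known ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
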