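Package: immunoscape
Title: Immunophenotype and Antigenome Characterization of Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize the intratumoral immune landscape and the
    tumor antigenome from bulk expression and somatic mutation data. Derives
    cell-type-specific immune metagenes from labeled reference expression
    profiles, scores tumor-infiltrating lymphocyte enrichment by single-sample
    gene set enrichment (ssGSEA) and a weighted relative-abundance statistic,
    enumerates candidate neo-antigens (mutant 8-11-mer peptides filtered by
    predicted HLA binding rank and reference-proteome novelty), calls
    cancer-germline antigens against a normal-tissue baseline, quantifies
    clonal heterogeneity from cancer-cell-fraction distributions, reconstructs
    a TIL-immunomodulator correlation network annotated with survival
    statistics, and fits a lasso-regularized model of tumor immunogenicity.
    A seeded synthetic-cohort generator with planted ground truth makes every
    stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
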