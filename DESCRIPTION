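Package: enhancerDMR
Title: Differentially Methylated Enhancer Analysis for Neuronal Bisulfite Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted bisulfite sequencing of neuronal
    enhancers: per-cytosine methylation call import and quality filtering,
    covariate-adjusted robust linear modelling with empirical-Bayes variance
    moderation, detection of differentially methylated regions by
    hypergeometric enrichment of top-decile differentially methylated
    cytosines, reference-based neuronal-subtype deconvolution, a CpH
    epigenetic clock with aging-acceleration testing, and integration of
    enhancer methylation with target-gene expression through chromatin
    interaction maps. Includes a synthetic-cohort generator with ground
    truth so every stage can be validated without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    edgeR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
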