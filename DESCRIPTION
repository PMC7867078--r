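Package: mirCascade
Title: Multi-Omics Cascade for Nominating Epigenetically Modulated miRNA
    Regulators
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a multi-omics inference cascade that nominates
    candidate miRNA regulators of ER-alpha signaling from qPCR miRNome
    profiling. Starting from cycle-threshold (CT) matrices, the package
    performs -ddCt relative quantification with detection-bound filtering
    and Venn decomposition of expression classes, aggregates multi-tool
    miRNA target predictions into consensus targets filtered by HIT count
    and observed/expected ratio, matches consensus targets against
    transcriptome fold changes in the anti-correlated direction, overlays
    ER-alpha/LSD1 immunoprecipitation interactome calls to derive bona fide
    interactors, and ranks convergent candidate miRNAs. A paired
    tumor/normal cohort module classifies patients from immunohistochemistry
    parameters and contrasts treatment response between ER-alpha-positive
    and ER-alpha-negative groups. A synthetic-data module generates all
    pipeline inputs with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: GeneExpression, miRNA, qPCR, GeneTarget, Transcriptomics
RoxygenNote: 7.3.3
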