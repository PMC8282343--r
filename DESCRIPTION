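Package: sigQTL
Title: Transcriptional Signatures and Gene-Environment Interaction eQTL
    Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking environmental and clinical phenotypes to
    gene regulation in blood transcriptomes. Implements elastic-net
    "transcriptional signature" models that denoise and impute phenotypes
    from RNA-seq expression, cis-eQTL mapping with adaptive permutations
    and a beta-distribution approximation of the permutation null,
    and genotype-by-environment (GxE) interaction-eQTL mapping against
    quantile-normalized signatures with a pooled permutation empirical
    null and Storey q-value FDR control. A synthetic cohort generator
    with exported ground truth supports end-to-end calibration and
    parameter-recovery validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    Matrix,
    BiocGenerics,
    SummarizedExperiment,
    S4Vectors,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
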