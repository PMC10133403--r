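Package: mmlda
Title: Multi-Modal Topic Modeling of Disease Omics with Missing-Modality
    Imputation and Path-Based Target Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Soft-clusters human diseases by jointly modeling several
    disease-omics modalities (altered expression, biomarkers, genetic
    variation, microbiota) with a multi-modal latent Dirichlet allocation
    fitted by uncollapsed Gibbs sampling. A deliberately removed modality of
    a disease is imputed from the shared per-disease topic weights, and the
    sampling frequency of the imputed tokens is thresholded with the Youden
    index to yield latent omics features and latent disease-disease
    similarities. The topic count is chosen by Louvain community detection
    on shared-feature graphs. A companion classifier scores directed pathway
    paths rooted at drug targets by normalized Levenshtein similarity and
    predicts therapeutic indications and side effects with bagged
    gradient-boosted trees. Seeded synthetic-data generators emulate the
    corpus, pathway and annotation inputs end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
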