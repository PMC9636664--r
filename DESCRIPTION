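Package: tadconcord
Title: Comparative Analysis of Topologically Associating Domain Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies concordance and robustness across two or more
    topologically associating domain (TAD) datasets called on a common
    genomic region. Provides TAD interval I/O on a shared binning frame,
    count and size statistics, tolerance-based shared-boundary and
    shared-domain comparisons, the Measure of Concordance (MoC) pairwise,
    one-vs-all and averaged all-vs-all, PCA and t-SNE similarity
    embeddings of TAD datasets, Hi-C contact-matrix ingestion with five
    balancing methods (VC, SQRT-VC, KR, ICE, SCN), a synthetic TAD and
    contact-matrix generator with perturbation operators for validation,
    and a reporting front end that writes a full machine-readable
    comparison as CSV/JSON.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    Rtsne,
    rhdf5
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
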