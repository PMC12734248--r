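Package: flytrace
Title: Geographic Origin Tracing of Bactrocera dorsalis Incursions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tracing the geographic origin of oriental fruit fly
    (Bactrocera dorsalis) specimens intercepted outside their native range.
    Implements three complementary evidence streams: (1) discriminant
    analysis of principal components (DAPC) on aligned COI DNA barcodes,
    with unsupervised haplotype clustering, cross-validated selection of the
    number of retained principal components, posterior assignment of query
    barcodes, and sampling-effort-normalized regional profiles per cluster;
    (2) diagnostic nuclear SNP panel discovery by recursive feature
    elimination with a random-forest learner, distilled into a compact
    decision tree applied under a conservative read-depth mask; and
    (3) population structure inference from genotype likelihoods via an
    iterative individual-allele-frequency covariance estimator with PCA and
    neighbour-joining trees. A synthetic-data module simulates
    two-population nuclear genotypes and region-structured mitochondrial
    haplotype alignments (including planted mitonuclear discordance) so the
    whole pipeline can be exercised and validated without external data.
    Per-specimen calls from the three methods are combined into consensus
    origin records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    MASS,
    randomForest,
    stats,
    utils,
    vcfR
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
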