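Package: coldstab
Title: Cold-Storage Stability Assessment for Droplet Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality-control and degradation statistics for droplet
    single-cell RNA-seq experiments in which intact tissue pieces are held
    in cold hypothermic preservation before dissociation. Implements a
    read-depth-normalized UMI statistic with a three-way
    ambient/debris/cellular droplet classification, per-barcode
    exonic/intronic read-category fractions with quartile trend analysis,
    standard cell and gene filters, mitochondrial-percentage metrics,
    similarity-based reassignment of high-mitochondrial cells to annotated
    cell types, per-cell-type mitochondrial fold-change tables with
    small-stratum masking, cell-type composition tests across time points
    and donors, gene-wise marginal R-squared variance partitioning,
    cross-organ subsampled hierarchical clustering, and bulk versus
    single-cell pseudo-bulk differential expression by Wilcoxon tests with
    Benjamini-Hochberg correction. A synthetic droplet-experiment
    generator with injectable degradation effects provides ground truth
    for every downstream statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
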