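Package: methkin
Title: Kinship-Aware Differential DNA Methylation Analysis for RRBS Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential DNA methylation analysis for reduced-representation
    bisulfite sequencing (RRBS) count data from families of related
    individuals. Reads Bismark-style per-CpG coverage files, applies a
    coverage / variance / extreme-methylation / C-T-SNP filter cascade, and
    tests each CpG site with a binomial mixed model on the logit scale whose
    random effect carries a genetic-relatedness (kinship) covariance, so that
    family structure does not masquerade as a treatment effect. Includes
    Storey q-value false discovery rate estimation, windowed calling of
    differentially methylated regions, gene annotation and Fisher gene-set
    enrichment, global-pattern statistics (hierarchical clustering, PCA,
    ANOSIM), SNP-based parentage assignment and genomic-relationship-matrix
    estimation, and a synthetic-data generator emulating a split-family
    two-environment rearing design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
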