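Package: regqtl
Title: Cis-Regulatory QTL Mapping, Cross-Cell-Type Sharing, and GWAS Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping cis expression and splicing quantitative trait
    loci (eQTLs/sQTLs) across immune cell types, quantifying cross-cell-type
    sharing of genetic effects with a multivariate empirical-Bayes shrinkage
    model (posterior mean effects and local false sign rates), and
    colocalizing regulatory QTLs with GWAS loci via Wakefield approximate
    Bayes factors. Includes permutation-based QTL significance with a
    beta-distribution approximation, Storey q-values and pi1 replication
    statistics, greedy GWAS locus clumping, LeafCutter-style intron-cluster
    harmonization, LD-bin diagnostics for cell-type specificity, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
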