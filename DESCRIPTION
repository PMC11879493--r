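Package: shadenet
Title: Gene-Allele Marker GWAS and Expression Network Analysis for
    Shade-Tolerance Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of shade-tolerance
    indicators in biparental recombinant inbred line (RIL) populations.
    Computes the shade-tolerance index (STI) and relative pith cell length
    (RCL) from raw plot and micrograph records, estimates variance components
    and broad-sense heritability with and without genotype-by-environment
    interaction, assembles within-gene SNP haplotypes into multi-allelic
    gene-allele sequence markers (GASMs), runs a restricted two-stage
    multilocus GWAS with a heritability cap and contribution accounting,
    predicts cross recombination potential from the fitted gene-allele matrix
    under free-assortment and linkage models, calls differentially expressed
    genes by fold-change and t-test thresholds with Venn partitioning, and
    summarises protein-protein interaction edge lists (confidence filtering,
    components, hub statistics). A seeded synthetic-data module generates RIL
    genotypes by single-seed descent, multi-environment phenotypes with
    controlled heritability, and negative-binomial expression matrices so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    igraph,
    vcfR,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
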