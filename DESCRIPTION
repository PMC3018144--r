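Package: anchornet
Title: Haplotype Maps, cis-eQTL Mapping and Anchored Co-Expression
    Modules in Inbred Strain Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated genomics workflow for panels of inbred mouse
    strains: iterative construction of SNP-based haplotype blocks with a
    bounded-error consensus rule, tagging of copy-number variant regions by
    pooled multi-allelic R-squared, cis-eQTL mapping of expression traits on
    haplotype and CNVR genotypes with a relatedness-weighted permutation
    null, a permutation test of whether unsupervised expression clustering
    predicts a binary strain phenotype, moderated differential expression
    with Storey q-value FDR, and discovery, trimming and phenotype scoring
    of anchored co-expression modules validated in a recombinant inbred
    panel. A synthetic-data generator plants haplotype mosaics, cis and
    trans effects and a phenotype so every stage can be checked against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
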