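Package: mirInfluence
Title: Signed Regulatory Influence of miRNAs on Target Genes from Paired
    Tumor-Normal Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the sign and strength of each miRNA's regulatory
    influence on its target genes from paired tumor/normal expression
    profiles. Counts are RPM-normalized, differentially expressed miRNAs
    and genes are identified with an FDR-adjusted paired test, each
    miRNA's per-patient expression change is apportioned over its target
    genes, the regulation sign is taken from the Pearson correlation of
    apportioned miRNA changes with target-gene changes, local influences
    are normalized per gene, and miRNAs are ranked by a global influence
    score weighting local influence with protein-protein interaction
    degree centrality. Also classifies whether restoring a miRNA toward
    its normal level would alleviate or deteriorate each target gene's
    abnormal expression, and ships a seeded synthetic-data generator
    with planted signed regulations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
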