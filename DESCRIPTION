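Package: tipmapr
Title: Bulked-Segregant and Mixed-Model Mapping of a Recessive Fruit-Tip Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational discovery chain for a binary, recessively inherited
    fruit blossom-end (pointed tip) phenotype in tomato-style material: seeded
    simulation of an F2 cross with pooled bulk sequencing and of a structured
    diversity panel; SNP-index and delta-SNP-index bulked-segregant QTL mapping
    with sliding-window averaging and Monte-Carlo confidence bands under a
    no-QTL null; a single-variance-component linear mixed-model association
    scan with principal-component covariates, MAF/MAC filtering, Bonferroni
    thresholds and genomic-inflation diagnostics; windowed nucleotide
    diversity, between-group pi-ratio selective-sweep scanning with a
    genome-wide top-quantile threshold, pairwise LD r2 and haploblock
    extraction; plus minimal VCF/TSV interchange and a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    jsonlite,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
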