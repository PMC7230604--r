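Package: pleioband
Title: Cross-Phenotype SNP-Cluster Discovery at Cytoband Resolution
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative phenotype-genotype workflow that mines
    GWAS-catalog association tables for single-nucleotide polymorphisms
    linked to a configurable set of clinical phenotypes (diabetes,
    obesity/BMI, dyslipidemia, hypertension, obstructive sleep apnea),
    clusters them by cytoband, computes the exclusive multi-phenotype
    Venn partition of cytobands, and extracts SNP-clusters and candidate
    genes from regions shared by several phenotypes. Downstream stages
    provide annotation-term enrichment (hypergeometric, binomial or
    Fisher tests with Benjamini-Hochberg FDR), information-content-based
    semantic similarity between annotated entities over an ontology DAG
    (most-informative-common-ancestor similarity with best-match
    combiners), per-gene variant burden counting from VCFs with a
    pooled-median candidate-gene rule, and a normality-gated two-group
    expression comparison with mean-expression ranking. A synthetic-data
    module generates catalogs, ontologies, VCFs and expression matrices
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
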