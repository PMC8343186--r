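Package: chetscreen
Title: Family-Based Compound-Heterozygous Variant Prioritization and
    Quartile-Stratified Enrichment
Version: 0.1.0
Authors@R:
    person("chetscreen", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing germline compound-heterozygous candidate
    genes in quad pedigrees (two parents, two or more affected children) from a
    multi-sample VCF and a variant annotation table: Mendelian inheritance
    labeling from unphased genotypes, parent-branch rare-variant filter
    cascades (allele frequency, consequence class, cancer-driver screen),
    two-hit gene intersection, pathogenicity-predictor consensus, and
    protein-domain mapping of truncating alleles. Also implements the
    expression side of such studies: threshold-based differential-expression
    selection, single- and joint-gene quartile sample grouping, and
    hypergeometric gene-set over-representation with Benjamini-Hochberg
    adjustment. A seeded synthetic-data module generates complete pedigree /
    VCF / annotation / gene-set / count-matrix bundles with a planted causal
    compound-heterozygous gene so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    data.table,
    GenomicRanges,
    optparse,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    VariantAnnotation
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
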