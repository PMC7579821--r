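Package: holosplit
Title: Holobiont Transcriptome Partitioning and Gonadal Expression Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing de novo transcriptome assemblies from
    coral-dinoflagellate holobionts. Partitions assembled contigs into host,
    symbiont, and other classes from alignment evidence with GC-content
    diagnostics, reduces redundancy by greedy identity clustering at the
    nucleotide and protein levels, summarises assembly and annotation
    statistics, detects phase-specific upregulated genes across a staged
    gametogenic series in two sexes (TMM/CPM normalisation, per-gene one-way
    ANOVA with Benjamini-Hochberg adjustment, fold-change filters), and tests
    term over-representation with the hypergeometric tail. Ships a synthetic
    holobiont generator that emulates the statistical structure of gonadal
    RNA-seq data with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
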