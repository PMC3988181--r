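Package: coexmod
Title: Module Discovery in Gene Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-targeted discovery of functionally coherent gene modules
    (for example plant cell-wall biosynthesis modules) in genome-wide
    co-expression networks. Implements sample-redundancy weighting and
    weighted Pearson correlation, density-guided correlation cutoff
    selection, scale-free topology diagnostics, modularity-maximizing
    module detection by recursive spectral bisection with Kernighan-Lin
    refinement, per-module Gene Ontology enrichment by hypergeometric
    tests with Bonferroni and Benjamini-Hochberg correction, promoter
    extraction from genome FASTA and GFF3 annotation, exhaustive
    mismatch-tolerant k-mer motif overrepresentation analysis, and
    matching of discovered motifs against an IUPAC consensus catalog of
    known cis-regulatory elements. A synthetic-data generator produces
    expression compendia, annotations and genomes with planted structure
    so the whole pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
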