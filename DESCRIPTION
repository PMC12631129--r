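Package: junctionASE
Title: Junction-Read Based Alternative Splicing Analysis for Barcoded
    Single-Cell RNA-Seq
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects, classifies and quantifies alternative splicing events
    (cassette exons, alternative first/last exons, alternative 5'/3' splice
    sites, mutually exclusive exons, intron retention and unclassified
    events) from exon-exon junction reads in cell-barcoded, UMI-tagged
    alignments such as 10x Genomics 5' single-cell RNA-seq, with a bulk
    mode that skips UMI deduplication.  Percent-spliced-in (PSI) values
    carry exact Clopper-Pearson confidence intervals.  Downstream tools
    include an empirical-Bayes beta-binomial inferred-PSI matrix for
    embedding with a splicing-information-destroying permutation null,
    binomial-GLM likelihood-ratio tests for cell-type- or group-specific
    splicing with Benjamini-Hochberg correction, expression-matched
    Fisher enrichment tests, T-cell splicing distance and similarity
    indices, and a tumor-antigen chain that nominates atypical isoforms
    against normal references, applies the 50-nt nonsense-mediated-decay
    rule, enumerates proteome-unique 8-11-mer peptides, integrates
    external MHC binding ranks and computes the splice-derived tumor
    antigen burden (ATB).  A synthetic-data module generates toy genomes,
    annotations and tagged reads with planted events of every type and a
    machine-readable ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    cluster,
    knitr
Config/testthat/edition: 3
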