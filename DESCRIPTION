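Package: locrep
Title: Discovery and Analysis of Local Repeats in Genomic Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying local repeats (LRs): sequence families that
    recur discontinuously within a single genomic locus but rarely elsewhere
    in the genome. Provides transposable-element masking, de novo repeat
    discovery by k-mer seeding and bidirectional consensus extension,
    tandem-repeat detection and filtering, genome-wide consensus mapping with
    locality classification, length-normalized repeat-burden statistics
    against shuffled genomic nulls, multi-mapping-aware ChIP-Seq enrichment
    with a permutation-calibrated Poisson test, exact position-weight-matrix
    motif scanning, neighbor-joining phylogenetics with bootstrap support,
    and a synthetic-genome simulator that plants repeat families with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
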