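Package: scilite
Title: Single-Cell Combinatorial Indexing of Targeted Amplicons and
    Mitochondrial Heteroplasmy Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing and analysis of single-cell combinatorial-indexing
    targeted-expression (SCI-LITE) libraries: barcode and amplicon error
    correction, UMI-consensus allele calling, knee-plot cell calling,
    per-cell mitochondrial heteroplasmy quantification, barnyard doublet
    analysis and lineage-barcode tracing.  Includes a Wright-Fisher-style
    simulator of heteroplasmy dynamics in a dividing population under an
    inverse-sigmoid cell-fitness model, random-search fitting of the
    fitness parameters against observed joint heteroplasmy distributions,
    Kimura drift-distribution fitting with Monte-Carlo Kolmogorov-Smirnov
    goodness-of-fit testing, and a synthetic-data generator that emulates
    the library structure with full ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    MASS,
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
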