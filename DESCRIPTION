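Package: QCTcount
Title: Molecular Counting with Quantitative Counting Templates and
    Single-Gene NIPT Likelihood-Ratio Calling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Decodes Quantitative Counting Template (QCT) spike-ins from
    amplicon sequencing reads to count absolute input DNA molecules
    (genomic equivalents), uses per-reaction embedded molecular index
    (EMI) fingerprints to quantify cross-sample contamination and detect
    sample mixups, estimates cell-free DNA fetal fraction from paternally
    inherited SNVs, and calls fetal genotypes for paternal and recessive
    inheritance with a binomial likelihood-ratio model. Includes a
    synthetic-read simulator with ground truth for every stage, covering
    PCR amplification bias, sequencing error, cross-contamination and
    index misassignment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
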