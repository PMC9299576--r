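Package: cfRNAfrag
Title: Cell-Free RNA Fragmentomics and Tiered Transcript Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of cell-free RNA (cfRNA) sequencing libraries built by
    polyadenylation-ligation chemistry: read cleanup (3' adapter, poly(A) and
    quality trimming, length and N-content filters), a forward-strand
    best-stratum transcriptome aligner applied tier by tier across RNA
    biotypes (abundant-RNA depletion, miRNA with mature-position rules,
    tRNA/piRNA with priority tie-breaking, mRNA/lncRNA, other ncRNA),
    RPM and EM-based TPM quantification, and cfRNA fragmentomics: fragment
    length distributions (including the paired-read long-fragment rule),
    5'/3' terminal-base statistics and 256-entry 4-mer end-motif profiles.
    Includes a synthetic cfRNA library generator that models RNase-A-biased
    degradation (pyrimidine-preferring cleavage leaving 5'-OH/3'-P ends),
    polynucleotide-kinase-gated capture, in-silico depletion and library
    end chemistry, so every pipeline stage can be verified against ground
    truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
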