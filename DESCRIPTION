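Package: termstoich
Title: Internal Intrinsic Terminators and Transcript Stoichiometry in ABC
    Importer Operons
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for internal Rho-independent (intrinsic)
    transcription terminators located between genes of bacterial ABC importer
    operons. Surveys gene-cluster architecture around substrate-binding
    protein (SBP) genes, extracts strand-aware intergenic regions, finds the
    minimum-free-energy RNA stem-loop in each region with an embedded
    nearest-neighbor thermodynamic model (with an exhaustive enumeration
    oracle for verification), classifies candidate terminators into four
    structural types by their 3' U-rich tracts and stem defects, quantifies
    termination efficiency from Northern-blot band intensities and
    dual-reporter qPCR, and tests positional enrichment of stem-loops and
    promoters with exact hypergeometric statistics. A synthetic-data
    generator produces annotated genomes with embedded terminators and
    measurement tables with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
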