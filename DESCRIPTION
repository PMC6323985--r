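Package: cistromeqc
Title: Quality Control and Mappability Toolkit for ChIP-Seq Cistrome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for uniform processing of transcription-factor ChIP-seq
    peak data: genome mappability tracks via suffix-array minimal-unique-length
    computation, merging of peak sets from multiple peak callers into merged
    peaks, clusters and meta-clusters, capture-recapture population-size
    estimators (Chao, Lanumteang-Bohning, Zelterman, zero-truncated Poisson
    maximum likelihood, Chapman) with the derived false-negative and
    false-positive control metrics (FNCM, FPCM), the ENCODE library-complexity
    and strand cross-correlation metrics (NRF, PBC1, PBC2, NSC, RSC, FRiP),
    and position-weight-matrix binding-site prediction with exact
    p-value-to-score-threshold computation. Includes a synthetic-data
    generator so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
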