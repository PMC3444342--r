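Package: period3
Title: Period-3 Spectral Detection of Protein-Coding Regions in DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate protein-coding regions in DNA sequences by
    exploiting their characteristic three-base periodicity. Sequences are
    converted to Voss binary indicator vectors (one per nucleotide), and the
    spectral power at normalized frequency 1/3 is computed in a sliding
    window with a multiplication-free Goertzel recursion (or a full-FFT
    single-bin backend), producing a genome-browser-ready power track.
    Includes threshold-based region calling against interval truth sets,
    deterministic chunked parallel scanning whose output is identical to the
    serial scan, a synthetic codon-biased sequence generator for end-to-end
    validation, and FASTA/BED/bedGraph/WIG input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    parallel,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
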