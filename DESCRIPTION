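Package: motubar
Title: Paired-End COI Metabarcoding of Host-Parasitoid Communities
Version: 0.1.0
Authors@R: person("Milan", "Kral", email = "milan.kral@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a DNA-metabarcoding workflow for
    identifying host-parasitoid mock communities from non-overlapping
    paired-end COI reads: MID demultiplexing with run-based quality
    truncation, de-novo two-parent chimera screening, abundance-ordered
    greedy centroid clustering at 97 percent identity with per-sample
    singleton removal, dual-read consensus taxonomic classification with a
    lowest-common-ancestor fallback, and an evaluation layer covering
    mock-community recovery, a three-method identification-success
    comparison with equal-proportions tests, and a BIN-versus-morphospecies
    reference-library audit. A synthetic-data module generates reference
    libraries, mock-community designs, and error-bearing paired reads with
    full ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
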