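#' Load a packaged fixture table
#'
#' Two small benchmark tables ship with the package as plain TSV:
#'
#' * `table1` -- identification success of three methods (morphological,
#'   standard barcoding, metabarcoding) at family/genus/species level for 22
#'   mock-sample individuals. Success percentages are as published; the
#'   integer success counts are reconstructed from the percentages (out of
#'   n = 22) and flagged as such in `n_success_reconstructed`.
#' * `table2` -- the reference-library audit: per taxon group (24 parasitoid
#'   rows, 19 host rows), barcoded specimen counts, developmental-stage
#'   counts, morphospecies and BIN counts, and the percentage of BINs
#'   assigned at family/subfamily/genus/species rank. Sum rows are not
#'   stored; [library_completeness()] recomputes them.
#'
#' @param name `"table1"` or `"table2"`.
#' @return Data frame.
#' @export
load_fixture_tables <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "motubar",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (name == "table1") df$n_success_reconstructed <- as.logical(df$n_success_reconstructed)
  df
}
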