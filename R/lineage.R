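#' Taxonomic rank schema
#'
#' The ordered rank schema used throughout the package. Lineages are
#' character vectors of taxon names read shallow-to-deep against this schema;
#' a lineage may stop early (a partial assignment) but may not skip ranks
#' (the prefix property).
#'
#' @export
LINEAGE_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                   "subfamily", "genus", "species")

#' Construct and validate a lineage
#'
#' @param names Character vector of taxon names, shallow to deep. Empty
#'   strings and `NA`s are only allowed as a trailing run and are dropped.
#' @return Character vector of class `lineage` satisfying the prefix
#'   property (no internal gaps, at most `length(LINEAGE_RANKS)` ranks).
#' @export
lineage <- function(names = character()) {
  names <- as.character(names)
  absent <- is.na(names) | names == ""
  if (any(absent)) {
    first <- which(absent)[1]
    if (!all(absent[first:length(names)]))
      stop("lineage violates the prefix property: rank ", first,
           " is absent but a deeper rank is named")
    names <- names[seq_len(first - 1)]
  }
  if (length(names) > length(LINEAGE_RANKS))
    stop("lineage has ", length(names), " ranks; schema allows at most ",
         length(LINEAGE_RANKS))
  structure(names, class = "lineage")
}

#' Parse a semicolon-delimited lineage string
#'
#' Accepts plain names (`Insecta;Lepidoptera`) and, when `strip_prefixes`
#' is TRUE, `k__`-style rank prefixes. Trailing empty fields are dropped;
#' internal empty fields are an error.
#'
#' @param x Single lineage string.
#' @param sep Field separator, default `";"`.
#' @param strip_prefixes Drop leading `x__` rank markers if present.
#' @return A [lineage()].
#' @export
parse_lineage <- function(x, sep = ";", strip_prefixes = TRUE) {
  if (length(x) != 1L) stop("parse_lineage() expects a single string")
  if (is.na(x) || x == "") return(lineage())
  parts <- strsplit(x, sep, fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (strip_prefixes) parts <- sub("^[a-z]__", "", parts)
  lineage(parts)
}

#' Serialize a lineage
#'
#' @param x A [lineage()] or plain character vector.
#' @param sep Separator.
#' @param prefixes If TRUE, emit `k__Name;p__Name;...` style markers.
#' @return Single string.
#' @export
format_lineage <- function(x, sep = ";", prefixes = FALSE) {
  x <- as.character(x)
  if (prefixes && length(x) > 0) {
    tags <- substr(LINEAGE_RANKS[seq_along(x)], 1, 1)
    tags[LINEAGE_RANKS[seq_along(x)] == "subfamily"] <- "sf"
    x <- paste0(tags, "__", x)
  }
  paste(x, collapse = sep)
}

#' Longest common lineage prefix
#'
#' @param lineages A list of lineages (character vectors).
#' @return The deepest lineage that is a prefix of every input.
#' @export
lineage_common_prefix <- function(lineages) {
  if (length(lineages) == 0) return(lineage())
  lineages <- lapply(lineages, as.character)
  depth <- min(lengths(lineages))
  out <- character()
  for (d in seq_len(depth)) {
    names_d <- vapply(lineages, `[`, character(1), d)
    if (length(unique(names_d)) == 1L) out <- c(out, names_d[1]) else break
  }
  lineage(out)
}

#' Is `a` a prefix of `b`?
#'
#' @param a,b Lineages (character vectors).
#' @return Logical scalar.
#' @export
is_lineage_prefix <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  length(a) <= length(b) && all(a == b[seq_along(a)])
}
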