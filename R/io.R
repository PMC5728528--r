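#' Read a FASTA file
#'
#' Sequences are uppercased on ingest and `U` is mapped to `T`.
#'
#' @param path FASTA file (gzip-transparent).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  # BStringSet first: DNAStringSet would reject/mangle lowercase RNA-style
  # input before the U -> T mapping can run
  x <- Biostrings::readBStringSet(path)
  out <- chartr("U", "T", toupper(as.character(x)))
  Biostrings::DNAStringSet(out) # validates the IUPAC alphabet
  out <- unname(out)
  names(out) <- names(x)
  # keep only the first whitespace-delimited token of the header
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

phred_offset <- 33L

qual_to_int <- function(q) utf8ToInt(q) - phred_offset

int_to_qual <- function(q) intToUtf8(q + phred_offset)

check_phred33 <- function(quals, path) {
  codes <- utf8ToInt(paste(quals, collapse = ""))
  if (length(codes) && min(codes) >= 64 && max(codes) > 75)
    stop("quality strings in '", path, "' look phred+64 encoded; ",
         "only phred+33 is supported")
  if (length(codes) && min(codes) < phred_offset)
    stop("quality character below '!' in '", path, "': not phred+33")
  invisible(TRUE)
}

#' Read a FASTQ file (phred+33)
#'
#' A hand-rolled 4-line-record reader so malformed records are rejected with
#' positional diagnostics rather than silently skipped. Phred+64 input is
#' rejected with a clear error. Bases are uppercased, `U` mapped to `T`.
#'
#' @param path FASTQ file (gzip-transparent).
#' @return Data frame with columns `read_id`, `bases`, `quals`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("FASTQ '", path, "' has ", length(lines),
         " lines, not a multiple of 4 (truncated record at end of file)")
  n <- length(lines) %/% 4
  if (n == 0) return(data.frame(read_id = character(), bases = character(),
                                quals = character(), stringsAsFactors = FALSE))
  heads <- lines[seq(1, length(lines), 4)]
  bases <- lines[seq(2, length(lines), 4)]
  plus <- lines[seq(3, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad))
    stop("FASTQ '", path, "' record ", bad[1], ": header does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("FASTQ '", path, "' record ", bad[1], ": separator line does not start with '+'")
  bad <- which(nchar(bases) != nchar(quals))
  if (length(bad))
    stop("FASTQ '", path, "' record ", bad[1], " ('",
         sub("^@", "", heads[bad[1]]), "'): sequence length ",
         nchar(bases[bad[1]]), " != quality length ", nchar(quals[bad[1]]))
  check_phred33(quals, path)
  ids <- sub("\\s.*$", "", sub("^@", "", heads))
  data.frame(read_id = ids,
             bases = toupper(chartr("U", "T", bases)),
             quals = quals, stringsAsFactors = FALSE)
}

#' Write a FASTQ file (phred+33)
#'
#' @param reads Data frame with `read_id`, `bases`, `quals`.
#' @param path Output path (a `.gz` suffix enables compression).
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$bases) == nchar(reads$quals)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$bases, "\n+\n", reads$quals),
             con, sep = "\n")
  invisible(path)
}

strip_mate_suffix <- function(ids) sub("(/[12]|[_ ][12])$", "", ids)

#' Read a pair of FASTQ files and match mates by read id
#'
#' Mates are matched by read id after stripping `/1`-style mate suffixes;
#' pairs are yielded in forward-file order and unpaired ids are reported.
#'
#' @param forward,reverse FASTQ paths.
#' @return List with `pairs` (data frame: `read_id`, `f_bases`, `f_quals`,
#'   `r_bases`, `r_quals`) and `orphans` (character vector of unmatched ids).
#' @export
read_fastq_pair <- function(forward, reverse) {
  f <- read_fastq(forward)
  r <- read_fastq(reverse)
  f$read_id <- strip_mate_suffix(f$read_id)
  r$read_id <- strip_mate_suffix(r$read_id)
  if (anyDuplicated(f$read_id))
    stop("duplicate read id '", f$read_id[duplicated(f$read_id)][1],
         "' in '", forward, "'")
  if (anyDuplicated(r$read_id))
    stop("duplicate read id '", r$read_id[duplicated(r$read_id)][1],
         "' in '", reverse, "'")
  idx <- match(f$read_id, r$read_id)
  keep <- !is.na(idx)
  pairs <- data.frame(read_id = f$read_id[keep],
                      f_bases = f$bases[keep], f_quals = f$quals[keep],
                      r_bases = r$bases[idx[keep]], r_quals = r$quals[idx[keep]],
                      stringsAsFactors = FALSE)
  orphans <- c(f$read_id[!keep], setdiff(r$read_id, f$read_id))
  list(pairs = pairs, orphans = orphans)
}

#' Read a taxonomy table
#'
#' Two-column TSV: record id, semicolon-delimited lineage (shallow to deep).
#' Trailing empty lineage fields are dropped; internal gaps, duplicate ids,
#' and lineages deeper than the rank schema are rejected.
#'
#' @param path TSV path.
#' @return Named list mapping record id to [lineage()].
#' @export
read_taxonomy_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(structure(list(), names = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop("taxonomy table '", path, "' line ", bad[1], ": expected 2 tab-separated columns")
  ids <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("taxonomy table '", path, "': duplicate record id '",
         ids[duplicated(ids)][1], "'")
  lineages <- lapply(seq_along(parts), function(i) {
    tryCatch(parse_lineage(parts[[i]][2]),
             error = function(e) stop("taxonomy table '", path, "' line ", i,
                                      " (", ids[i], "): ", conditionMessage(e)))
  })
  names(lineages) <- ids
  lineages
}

#' Write a taxonomy table
#'
#' @param lineages Named list of lineages (record id -> character vector).
#' @param path Output TSV path.
#' @param prefixes Emit `k__`-style rank markers.
#' @export
write_taxonomy_table <- function(lineages, path, prefixes = FALSE) {
  writeLines(paste0(names(lineages), "\t",
                    vapply(lineages, format_lineage, character(1),
                           prefixes = prefixes)),
             path)
  invisible(path)
}

#' Assemble a MOTU table
#'
#' @param motu_id Character vector of cluster ids.
#' @param counts Integer matrix (MOTUs x samples) with sample column names.
#' @param lineage Character vector of serialized lineages (one per MOTU).
#' @param category Character vector in
#'   `host|parasitoid|putative_symbiont|contaminant|unassigned`.
#' @return Data frame of class `motu_table`: `motu_id`, one column per
#'   sample, `lineage`, `category`.
#' @export
motu_table <- function(motu_id, counts, lineage, category) {
  counts <- as.matrix(counts)
  stopifnot(length(motu_id) == nrow(counts), !anyDuplicated(motu_id),
            length(lineage) == length(motu_id),
            length(category) == length(motu_id),
            all(counts >= 0), all(counts == round(counts)),
            !is.null(colnames(counts)))
  ok <- category %in% c("host", "parasitoid", "putative_symbiont",
                        "contaminant", "unassigned")
  if (!all(ok)) stop("unknown MOTU category '", category[!ok][1], "'")
  out <- data.frame(motu_id = motu_id, stringsAsFactors = FALSE)
  for (s in colnames(counts)) out[[s]] <- as.integer(counts[, s])
  out$lineage <- lineage
  out$category <- category
  class(out) <- c("motu_table", "data.frame")
  out
}

#' Write a MOTU table as TSV
#'
#' @param table A [motu_table()].
#' @param path Output path.
#' @export
write_motu_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MOTU table written by [write_motu_table()]
#'
#' @param path TSV path.
#' @return A [motu_table()].
#' @export
read_motu_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  need <- c("motu_id", "lineage", "category")
  if (!all(need %in% names(df)))
    stop("MOTU table '", path, "' lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  samples <- setdiff(names(df), need)
  counts <- as.matrix(df[samples])
  storage.mode(counts) <- "integer"
  colnames(counts) <- samples
  motu_table(df$motu_id, counts, df$lineage, df$category)
}

#' Write a truth manifest
#'
#' @param manifest Data frame with `read_id`, `specimen_id`, `sample_id`,
#'   `is_chimera`, `parent_a`, `parent_b`.
#' @param path Output TSV path.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a truth manifest
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  m$is_chimera <- as.logical(m$is_chimera)
  m
}
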