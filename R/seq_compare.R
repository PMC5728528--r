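#' Semi-global pairwise alignment with percent identity
#'
#' Dynamic-programming alignment with free terminal gaps on either sequence
#' (appropriate when one sequence is a fragment of the other), scoring
#' +1 match, -1 mismatch, -2 per gap position. Identity is computed over the
#' aligned columns only (terminal gaps excluded); internal gap columns count
#' as mismatches. IUPAC ambiguity codes match any compatible base.
#'
#' Score ties are resolved by a fixed additive rule (fewest aligned columns,
#' then most matches), which makes the reported identity a deterministic
#' function of the sequence pair.
#'
#' @param query,target Non-empty IUPAC DNA strings.
#' @return An object of class `alignment_result`: a list with
#'   `identity_pct`, `aligned_cols`, `matches`, `score`, logical
#'   `match_vector` (one flag per aligned column), and 0-based half-open
#'   `query_span` / `target_span`.
#' @examples
#' align_identity("ACGTACGT", "ACGTACGT")$identity_pct # 100
#' @export
align_identity <- function(query, target) {
  res <- .align_core(toupper(query), toupper(target))
  res$match_vector <- as.logical(res$match_vector)
  structure(res, class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment: identity %.2f%% over %d cols, score %d, q[%d,%d) t[%d,%d)>\n",
              x$identity_pct, x$aligned_cols, x$score,
              x$query_span[1], x$query_span[2],
              x$target_span[1], x$target_span[2]))
  invisible(x)
}

#' Percent identity of a query against one or many targets
#'
#' Identity-only fast path of [align_identity()] (same DP, no traceback).
#'
#' @param query Single DNA string.
#' @param targets Character vector of DNA strings.
#' @return Numeric vector of identities in `[0, 100]`, one per target.
#' @export
seq_identity <- function(query, targets) {
  if (length(targets) == 0) return(numeric())
  unname(.identity_many(toupper(query), toupper(targets))[, "identity_pct"])
}

#' Reverse complement with IUPAC support
#'
#' @param x Character vector of IUPAC DNA strings.
#' @return Reverse complements; `revcomp(revcomp(x)) == x`.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Build a k-mer index over reference sequences
#'
#' Every sequence of length >= k is indexed under all of its distinct
#' k-words. The index is used as a shared-word prefilter before full
#' alignment.
#'
#' @param seqs Character vector of DNA sequences.
#' @param ids Record identifiers (default names of `seqs` or positions).
#' @param k Word length, default 8.
#' @return An object of class `kmer_index`.
#' @export
kmer_index <- function(seqs, ids = NULL, k = 8) {
  if (is.null(ids)) ids <- if (!is.null(names(seqs))) names(seqs) else as.character(seq_along(seqs))
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  env <- new.env(hash = TRUE, parent = emptyenv())
  idx <- structure(list(k = k, postings = env, ids = character()),
                   class = "kmer_index")
  for (i in seq_along(seqs)) idx <- kmer_add(idx, seqs[i], ids[i])
  idx
}

seq_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Add one sequence to a k-mer index
#'
#' @param index A [kmer_index()].
#' @param seq DNA string.
#' @param id Record identifier (must be new).
#' @return The updated index (the posting environment is shared by
#'   reference; reassign the return value anyway for the id list).
#' @export
kmer_add <- function(index, seq, id) {
  stopifnot(inherits(index, "kmer_index"))
  if (id %in% index$ids) stop("duplicate record id '", id, "' in k-mer index")
  pos <- length(index$ids) + 1L # postings hold integer positions
  for (w in seq_kmers(seq, index$k)) {
    index$postings[[w]] <- c(index$postings[[w]], pos)
  }
  index$ids <- c(index$ids, id)
  index
}

#' Rank candidate references by shared distinct k-words
#'
#' @param query DNA string.
#' @param index A [kmer_index()].
#' @param top_n Maximum number of candidates to return.
#' @return Character vector of record ids ordered by shared-distinct-word
#'   count (descending; ties broken by record id). References sharing zero
#'   words are never returned.
#' @export
search_candidates <- function(query, index, top_n = 20) {
  stopifnot(inherits(index, "kmer_index"))
  words <- seq_kmers(query, index$k)
  if (length(words) == 0) return(character())
  hits <- unlist(mget(words, envir = index$postings, ifnotfound = list(NULL)),
                 use.names = FALSE)
  if (length(hits) == 0) return(character())
  counts <- tabulate(hits, nbins = length(index$ids))
  nz <- which(counts > 0)
  ord <- nz[order(-counts[nz], index$ids[nz], method = "radix")]
  index$ids[utils::head(ord, top_n)]
}
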