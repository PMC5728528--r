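#' Quality-control parameters
#'
#' Defaults follow the benchmark workflow: a base is *bad* iff its phred
#' score is <= 20 (the threshold names the worst unacceptable score); a read
#' is truncated before the first run of more than 3 consecutive bad bases;
#' mates shorter than 100 nt after truncation drop the pair; at most 1 MID
#' mismatch is tolerated (the source tooling's fractional 1.5-error budget
#' only differs for error-correcting codes).
#'
#' @param bad_quality_max Phred threshold; a base is bad iff Q <= this.
#' @param max_bad_run Longest tolerated run of consecutive bad bases.
#' @param min_length Minimum mate length after truncation.
#' @param max_mid_errors MID mismatch budget.
#' @return List of class `qc_params`.
#' @export
qc_params <- function(bad_quality_max = 20, max_bad_run = 3,
                      min_length = 100, max_mid_errors = 1) {
  stopifnot(bad_quality_max >= 0, max_bad_run >= 0, min_length >= 1,
            max_mid_errors >= 0)
  structure(list(bad_quality_max = bad_quality_max, max_bad_run = max_bad_run,
                 min_length = min_length, max_mid_errors = max_mid_errors),
            class = "qc_params")
}

# Hamming distance over the MID window; N (or any non-ACGT base) on the read
# counts as a mismatch unless identical to the MID character.
mid_distance <- function(prefix, mid) {
  a <- strsplit(prefix, "")[[1]]
  b <- strsplit(mid, "")[[1]]
  sum(a != b)
}

#' Assign a forward read to a sample by its MID
#'
#' Compares the first `nchar(mid)` bases against each MID by Hamming
#' distance. The unique sample at minimal distance <= `max_mid_errors` wins;
#' two MIDs tied at the minimal acceptable distance make the read ambiguous.
#'
#' @param bases Forward read sequence (MID still attached).
#' @param mids Named character vector, sample id -> MID.
#' @param params A [qc_params()].
#' @return List with `sample_id` (NA if unmatched) and `reason`
#'   (`"ok"`, `"mid_unmatched"`, or `"mid_ambiguous"`).
#' @export
assign_sample <- function(bases, mids, params = qc_params()) {
  width <- nchar(mids[1])
  stopifnot(all(nchar(mids) == width), !anyDuplicated(unname(mids)),
            !is.null(names(mids)))
  prefix <- substr(bases, 1, width)
  if (nchar(prefix) < width)
    return(list(sample_id = NA_character_, reason = "mid_unmatched"))
  d <- vapply(mids, mid_distance, numeric(1), prefix = prefix)
  dmin <- min(d)
  if (dmin > params$max_mid_errors)
    return(list(sample_id = NA_character_, reason = "mid_unmatched"))
  hits <- names(mids)[d == dmin]
  if (length(hits) > 1)
    return(list(sample_id = NA_character_, reason = "mid_ambiguous"))
  list(sample_id = hits, reason = "ok")
}

# Position before the first run of more than max_bad_run bad bases;
# returns the kept length (nchar if no such run).
truncation_length <- function(qint, bad_quality_max, max_bad_run) {
  bad <- qint <= bad_quality_max
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths > max_bad_run)
  if (length(hit) == 0) length(qint) else starts[hit[1]] - 1L
}

#' Truncate a read at the first long run of bad-quality bases
#'
#' A base is bad iff its phred score is <= `bad_quality_max`; the read is
#' cut immediately before the first run of more than `max_bad_run`
#' consecutive bad bases. Idempotent; reads with no such run are unchanged.
#'
#' @param bases,quals Sequence and phred+33 quality string.
#' @param params A [qc_params()].
#' @return List with truncated `bases` and `quals`.
#' @export
quality_truncate <- function(bases, quals, params = qc_params()) {
  stopifnot(nchar(bases) == nchar(quals))
  keep <- truncation_length(qual_to_int(quals), params$bad_quality_max,
                            params$max_bad_run)
  list(bases = substr(bases, 1, keep), quals = substr(quals, 1, keep))
}

#' Keep or drop a truncated read pair by length
#'
#' The pair is dropped when either mate is strictly shorter than
#' `min_length` (a 100-nt mate is kept).
#'
#' @param f_bases,r_bases Truncated mate sequences.
#' @param params A [qc_params()].
#' @return `"keep"`, `"too_short_forward"`, or `"too_short_reverse"`.
#' @export
length_filter <- function(f_bases, r_bases, params = qc_params()) {
  if (nchar(f_bases) < params$min_length) return("too_short_forward")
  if (nchar(r_bases) < params$min_length) return("too_short_reverse")
  "keep"
}

#' Demultiplex and quality-filter paired reads
#'
#' Per pair: MID assignment on the raw forward read (the MID is stripped on
#' acceptance), quality truncation of both mates, then the pairwise length
#' filter. Every input pair is accounted for exactly once in the report.
#'
#' @param pairs Data frame from [read_fastq_pair()]`$pairs`.
#' @param mids Named character vector, sample id -> MID.
#' @param params A [qc_params()].
#' @return List with `samples` (named list of per-sample pair data frames,
#'   MID stripped and mates truncated) and `report` (class `demux_report`:
#'   `accepted` named counts, `rejected` named counts by reason).
#' @export
demux_pairs <- function(pairs, mids, params = qc_params()) {
  width <- nchar(mids[1])
  n <- nrow(pairs)
  sample_id <- rep(NA_character_, n)
  reason <- rep("ok", n)

  # vectorized MID matching: distance of every read prefix to every MID
  prefixes <- substr(pairs$f_bases, 1, width)
  dmat <- matrix(0L, nrow = n, ncol = length(mids))
  for (j in seq_along(mids)) {
    midj <- strsplit(mids[j], "")[[1]]
    dj <- integer(n)
    for (p in seq_len(width))
      dj <- dj + (substr(prefixes, p, p) != midj[p])
    dmat[, j] <- dj
  }
  dmin <- do.call(pmin, as.data.frame(dmat))
  n_at_min <- rowSums(dmat == dmin)
  matched <- dmin <= params$max_mid_errors & n_at_min == 1
  ambiguous <- dmin <= params$max_mid_errors & n_at_min > 1
  reason[!matched & !ambiguous] <- "mid_unmatched"
  reason[ambiguous] <- "mid_ambiguous"
  sample_id[matched] <- names(mids)[apply(dmat[matched, , drop = FALSE], 1,
                                          which.min)]

  # strip MID, truncate both mates
  f_bases <- substr(pairs$f_bases, width + 1, nchar(pairs$f_bases))
  f_quals <- substr(pairs$f_quals, width + 1, nchar(pairs$f_quals))
  r_bases <- pairs$r_bases
  r_quals <- pairs$r_quals
  f_keep <- vapply(f_quals, function(q)
    truncation_length(qual_to_int(q), params$bad_quality_max,
                      params$max_bad_run), integer(1), USE.NAMES = FALSE)
  r_keep <- vapply(r_quals, function(q)
    truncation_length(qual_to_int(q), params$bad_quality_max,
                      params$max_bad_run), integer(1), USE.NAMES = FALSE)
  f_bases <- substr(f_bases, 1, f_keep)
  f_quals <- substr(f_quals, 1, f_keep)
  r_bases <- substr(r_bases, 1, r_keep)
  r_quals <- substr(r_quals, 1, r_keep)

  ok <- reason == "ok"
  too_short_f <- ok & nchar(f_bases) < params$min_length
  reason[too_short_f] <- "too_short_forward"
  too_short_r <- reason == "ok" & nchar(r_bases) < params$min_length
  reason[too_short_r] <- "too_short_reverse"

  accepted <- reason == "ok"
  samples <- lapply(setNames(names(mids), names(mids)), function(s) {
    i <- which(accepted & sample_id == s)
    data.frame(read_id = pairs$read_id[i],
               f_bases = f_bases[i], f_quals = f_quals[i],
               r_bases = r_bases[i], r_quals = r_quals[i],
               stringsAsFactors = FALSE)
  })
  acc_counts <- vapply(samples, nrow, integer(1))
  reasons <- c("mid_unmatched", "mid_ambiguous", "too_short_forward",
               "too_short_reverse")
  rej_counts <- vapply(reasons, function(r) sum(reason == r), integer(1))
  report <- structure(list(accepted = acc_counts, rejected = rej_counts,
                           input_pairs = n), class = "demux_report")
  stopifnot(sum(acc_counts) + sum(rej_counts) == n) # conservation
  list(samples = samples, report = report)
}

#' @export
print.demux_report <- function(x, ...) {
  cat("Demultiplexing report:", x$input_pairs, "input pairs\n")
  cat("  accepted:", paste(sprintf("%s=%d", names(x$accepted), x$accepted),
                           collapse = " "), "\n")
  cat("  rejected:", paste(sprintf("%s=%d", names(x$rejected), x$rejected),
                           collapse = " "), "\n")
  invisible(x)
}
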