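#' Dereplicate forward reads into unique sequences
#'
#' Exact-string grouping of quality-filtered forward reads, ordered by
#' abundance descending with ties broken by sequence lexicographic order
#' (stable across runs).
#'
#' @param bases Character vector of read sequences.
#' @param read_ids Read identifiers (default positions).
#' @return Data frame with `sequence`, `abundance`, and list-column
#'   `read_ids`, ordered for abundance-greedy clustering.
#' @export
dereplicate <- function(bases, read_ids = NULL) {
  if (is.null(read_ids)) read_ids <- as.character(seq_along(bases))
  stopifnot(length(read_ids) == length(bases))
  groups <- split(read_ids, bases)
  abundance <- lengths(groups)
  ord <- order(-abundance, names(groups), method = "radix")
  out <- data.frame(sequence = names(groups)[ord],
                    abundance = as.integer(abundance[ord]),
                    stringsAsFactors = FALSE)
  out$read_ids <- unname(groups[ord])
  out
}

#' De-novo two-parent chimera screen
#'
#' A simplified re-implementation of abundance-aware de-novo chimera
#' detection. Each unique sequence is tested against candidate parents drawn
#' from more abundant uniques (abundance >= `skew` times the query's). The
#' query is split into `n_chunks` equal chunks; each chunk nominates
#' `top_parents_per_chunk` parents by shared 8-mers. For every ordered
#' parent pair, the breakpoint maximizing the identity between the query and
#' the spliced model `A[0:b] + B[b:]` is found from the two parents'
#' per-position match profiles. The verdict is chimeric iff the best model
#' identity is at least `min_model_identity`, exceeds the best single-parent
#' identity by at least `min_gain` points, and both parent segments span at
#' least `min_segment` nt. Ties in the breakpoint scan resolve to the
#' midpoint of the maximizing plateau.
#'
#' Match profiles are computed position-wise in amplicon register: forward
#' reads all start at the amplicon 5' end, and indel errors are out of
#' scope, so query position i corresponds to parent position i. (A
#' score-optimal free-end-gap alignment would abandon that register for
#' chimeras with a short minor segment and hide the splice.) Single-parent
#' identity uses the same per-position denominator as the two-parent model.
#'
#' @param uniques Dereplicated uniques ([dereplicate()]), abundance-ordered.
#' @param skew Parent/query abundance ratio floor (default 2).
#' @param n_chunks Chunks per query (default 4).
#' @param top_parents_per_chunk Parents nominated per chunk (default 4).
#' @param min_gain Identity points the model must gain over the best single
#'   parent (default 1).
#' @param min_model_identity Minimum model identity percentage (default 99).
#' @param min_segment Minimum parent segment length in nt (default 30).
#' @param k Word size for parent nomination (default 8).
#' @return Data frame of chimera calls: `query`, `parent_a`, `parent_b`,
#'   `breakpoint` (0-based: columns `[0, breakpoint)` from parent A),
#'   `model_identity_pct`, `best_single_identity_pct`, `verdict`
#'   (`chimeric`/`clean`). Queries with no eligible parents are clean.
#' @export
detect_chimeras <- function(uniques, skew = 2.0, n_chunks = 4,
                            top_parents_per_chunk = 4, min_gain = 1.0,
                            min_model_identity = 99.0, min_segment = 30,
                            k = 8) {
  n <- nrow(uniques)
  calls <- vector("list", n)
  if (n == 0) return(chimera_calls_frame(calls))
  # parents must satisfy abundance >= skew * query >= skew * 1
  parent_pool <- which(uniques$abundance >= max(skew, 1))
  if (length(parent_pool) == 0) return(chimera_calls_frame(calls))
  pool_index <- kmer_index(uniques$sequence[parent_pool],
                           ids = as.character(parent_pool), k = k)
  for (qi in seq_len(n)) {
    qseq <- uniques$sequence[qi]
    qlen <- nchar(qseq)
    qab <- uniques$abundance[qi]
    call <- list(query = qi, parent_a = NA_integer_, parent_b = NA_integer_,
                 breakpoint = NA_integer_, model_identity_pct = NA_real_,
                 best_single_identity_pct = NA_real_, verdict = "clean")
    any_eligible <- any(uniques$abundance[parent_pool] >= skew * qab &
                          parent_pool != qi)
    if (qlen >= 2 * min_segment && qlen >= k && any_eligible) {
      # chunk-wise parent nomination; near-duplicate parents (conspecific or
      # truncated variants of one already nominated, >= 97% in-register
      # identity) are collapsed so a short minor-parent segment is not
      # crowded out of the chunk's slots by redundant major-parent variants
      bounds <- round(seq(0, qlen, length.out = n_chunks + 1))
      cand <- character()
      for (ci in seq_len(n_chunks)) {
        chunk <- substr(qseq, bounds[ci] + 1, bounds[ci + 1])
        if (nchar(chunk) < k) next
        ranked <- search_candidates(chunk, pool_index,
                                    top_n = length(pool_index$ids))
        picked <- character()
        for (r in ranked) {
          if (length(picked) >= top_parents_per_chunk) break
          rs <- uniques$sequence[as.integer(r)]
          dup <- any(vapply(picked, function(p) {
            ps <- uniques$sequence[as.integer(p)]
            w <- min(nchar(rs), nchar(ps))
            mean(utf8ToInt(substr(rs, 1, w)) ==
                   utf8ToInt(substr(ps, 1, w))) >= 0.97
          }, logical(1)))
          if (!dup) picked <- c(picked, r)
        }
        cand <- union(cand, picked)
      }
      cand <- as.integer(cand)
      cand <- cand[cand != qi &
                     uniques$abundance[cand] >= skew * qab]
      if (length(cand) >= 1) {
        qchars <- utf8ToInt(qseq)
        profiles <- lapply(cand, function(p) {
          pseq <- uniques$sequence[p]
          w <- min(qlen, nchar(pseq))
          c(utf8ToInt(substr(pseq, 1, w)) == qchars[seq_len(w)],
            rep(FALSE, qlen - w))
        })
        singles <- vapply(profiles, function(pr) 100 * sum(pr) / qlen,
                          numeric(1))
        call$best_single_identity_pct <- max(singles)
        # a model can never exceed 100%, so a near-perfect single parent
        # settles the verdict without the breakpoint scan
        run_scan <- length(cand) >= 2 &&
          call$best_single_identity_pct + min_gain <= 100
        if (run_scan) {
          prefix <- lapply(profiles, cumsum)
          totals <- vapply(profiles, sum, integer(1))
          bks <- seq(min_segment, qlen - min_segment)
          best <- list(id = -Inf)
          for (ai in seq_along(cand)) for (bi in seq_along(cand)) {
            if (ai == bi) next
            model_matches <- prefix[[ai]][bks] + (totals[bi] - prefix[[bi]][bks])
            mx <- max(model_matches)
            if (100 * mx / qlen > best$id) {
              plateau <- bks[model_matches == mx]
              best <- list(id = 100 * mx / qlen,
                           a = cand[ai], b = cand[bi],
                           bk = plateau[ceiling(length(plateau) / 2)])
            }
          }
          if (is.finite(best$id)) {
            call$parent_a <- best$a
            call$parent_b <- best$b
            call$breakpoint <- best$bk
            call$model_identity_pct <- best$id
            if (best$id >= min_model_identity &&
                best$id >= call$best_single_identity_pct + min_gain)
              call$verdict <- "chimeric"
          }
        }
      }
    }
    calls[[qi]] <- call
  }
  chimera_calls_frame(calls)
}

chimera_calls_frame <- function(calls) {
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (length(calls) == 0)
    return(data.frame(query = integer(), parent_a = integer(),
                      parent_b = integer(), breakpoint = integer(),
                      model_identity_pct = numeric(),
                      best_single_identity_pct = numeric(),
                      verdict = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(calls, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
}

#' Abundance-ordered greedy centroid clustering
#'
#' Uniques are scanned in abundance order; each is compared to all existing
#' centroids (shared-word prefilter, then full alignment) and joins the
#' centroid of *highest* identity at or above the threshold (ties go to the
#' earliest-created centroid); otherwise it seeds a new centroid. Best-hit
#' (not first-hit) assignment keeps results independent of candidate
#' enumeration order. Clustering operates on forward reads; reverse mates
#' ride along by read id, and a centroid's reverse representative is the
#' mate of the first read carrying the centroid sequence.
#'
#' @param uniques Dereplicated (and chimera-filtered) uniques.
#' @param threshold_pct Identity threshold (default 97).
#' @param sample_of_read Named character vector read_id -> sample_id (used
#'   to fill per-sample counts); NULL puts all reads in one sample "S".
#' @param rev_of_read Named character vector read_id -> reverse-mate
#'   sequence (as sequenced); NULL leaves `centroid_rev` empty.
#' @param max_candidates Centroid candidates examined per unique (default
#'   20).
#' @param min_overlap Minimum aligned columns for a membership decision
#'   (default 100, capped at the query/centroid length). Without this guard
#'   the free-terminal-gap identity is ~100% for chance short overlaps of
#'   unrelated sequences, making a bare percentage threshold meaningless.
#' @param k Word size of the centroid prefilter index.
#' @return Object of class `motu_set`: list with `motus` (data frame:
#'   `motu_id`, `centroid_fwd`, `centroid_rev`, `total`), `counts`
#'   (MOTU x sample integer matrix), `members` (list of read-id vectors).
#' @export
greedy_cluster <- function(uniques, threshold_pct = 97,
                           sample_of_read = NULL, rev_of_read = NULL,
                           max_candidates = 20, min_overlap = 100, k = 8) {
  n <- nrow(uniques)
  samples <- if (is.null(sample_of_read)) "S" else
    sort(unique(unname(sample_of_read)))
  centroid_seq <- character()
  centroid_rev <- character()
  members <- list()
  idx <- kmer_index(character(), ids = character(), k = k)
  assign_of <- integer(n)
  for (i in seq_len(n)) {
    qseq <- uniques$sequence[i]
    target <- 0L
    if (length(centroid_seq) > 0) {
      cand <- as.integer(search_candidates(qseq, idx, top_n = max_candidates))
      if (length(cand) > 0) {
        al <- .identity_many(qseq, centroid_seq[cand])
        ids <- al[, "identity_pct"]
        floor_cols <- pmin(min_overlap, nchar(qseq), nchar(centroid_seq[cand]))
        ok <- ids >= threshold_pct & al[, "aligned_cols"] >= floor_cols
        if (any(ok)) {
          best <- max(ids[ok])
          # ties -> earliest-created centroid
          target <- min(cand[ok][ids[ok] == best])
        }
      }
    }
    if (target == 0L) {
      centroid_seq <- c(centroid_seq, qseq)
      rid <- uniques$read_ids[[i]][1]
      rev_seq <- if (!is.null(rev_of_read)) unname(rev_of_read[rid]) else NA_character_
      centroid_rev <- c(centroid_rev, rev_seq)
      members[[length(members) + 1]] <- character()
      target <- length(centroid_seq)
      idx <- kmer_add(idx, qseq, as.character(target))
    }
    members[[target]] <- c(members[[target]], uniques$read_ids[[i]])
    assign_of[i] <- target
  }
  m <- length(centroid_seq)
  counts <- matrix(0L, nrow = m, ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (ci in seq_len(m)) {
    s <- if (is.null(sample_of_read)) rep("S", length(members[[ci]])) else
      unname(sample_of_read[members[[ci]]])
    tab <- table(s)
    counts[ci, names(tab)] <- as.integer(tab)
  }
  motu_ids <- sprintf("MOTU%04d", seq_len(m))
  structure(list(
    motus = data.frame(motu_id = motu_ids, centroid_fwd = centroid_seq,
                       centroid_rev = centroid_rev,
                       total = as.integer(rowSums(counts)),
                       stringsAsFactors = FALSE),
    counts = counts,
    members = setNames(members, motu_ids)), class = "motu_set")
}

#' @export
print.motu_set <- function(x, ...) {
  cat("<motu_set:", nrow(x$motus), "MOTUs,", sum(x$counts), "reads,",
      ncol(x$counts), "samples>\n")
  invisible(x)
}

#' Remove singleton clusters
#'
#' In `per_sample` mode (the default reading of "clusters with only one read
#' in individual samples"), per-sample counts equal to 1 are zeroed and
#' clusters whose total drops to 0 are removed. In `total` mode, clusters
#' with a total count of 1 are dropped.
#'
#' @param motus A `motu_set`.
#' @param mode `"per_sample"` or `"total"`.
#' @return Filtered `motu_set` (member read lists are pruned accordingly in
#'   `per_sample` mode only at the cluster level, not per read).
#' @export
remove_singletons <- function(motus, mode = c("per_sample", "total")) {
  mode <- match.arg(mode)
  counts <- motus$counts
  if (mode == "per_sample") {
    counts[counts == 1L] <- 0L
  } else {
    counts[rowSums(counts) == 1L, ] <- 0L
  }
  keep <- rowSums(counts) > 0
  structure(list(
    motus = transform(motus$motus[keep, , drop = FALSE],
                      total = as.integer(rowSums(counts[keep, , drop = FALSE]))),
    counts = counts[keep, , drop = FALSE],
    members = motus$members[keep]), class = "motu_set")
}
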