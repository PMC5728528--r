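#' Classifier parameters
#'
#' @param identity_window Retain hits with average identity within this many
#'   absolute percentage points of the maximum (default 0.5).
#' @param consensus_fraction Fraction of retained hits that must share a
#'   lineage prefix for assignment at a rank (default 0.5).
#' @param min_hit_identity Identity floor below which a reference does not
#'   count as matching a mate (default 80).
#' @param min_hit_overlap Minimum aligned columns for a mate match (default
#'   100, capped at the mate length); guards the free-terminal-gap identity
#'   against chance short overlaps.
#' @param lca_top_window Identity window (points) for the LCA fallback
#'   (default 10).
#' @param max_candidates References examined per mate after the shared-word
#'   prefilter (default 100).
#' @return List of class `classifier_params`.
#' @export
classifier_params <- function(identity_window = 0.5, consensus_fraction = 0.5,
                              min_hit_identity = 80, lca_top_window = 10,
                              max_candidates = 100, min_hit_overlap = 100) {
  stopifnot(identity_window >= 0, consensus_fraction > 0,
            consensus_fraction <= 1, min_hit_identity >= 0,
            min_hit_identity <= 100, lca_top_window >= 0,
            min_hit_overlap >= 1)
  structure(list(identity_window = identity_window,
                 consensus_fraction = consensus_fraction,
                 min_hit_identity = min_hit_identity,
                 lca_top_window = lca_top_window,
                 max_candidates = max_candidates,
                 min_hit_overlap = min_hit_overlap),
            class = "classifier_params")
}

#' Build an indexed reference set for classification
#'
#' @param records Data frame with `record_id`, `taxonomy` (semicolon
#'   lineage), `sequence`.
#' @param k Word size of the prefilter index (default 8).
#' @return Object of class `ref_index`.
#' @export
build_ref_index <- function(records, k = 8) {
  stopifnot(nrow(records) >= 1, !anyDuplicated(records$record_id))
  lineages <- lapply(records$taxonomy, parse_lineage)
  names(lineages) <- records$record_id
  structure(list(
    records = records,
    lineages = lineages,
    sequences = setNames(records$sequence, records$record_id),
    index = kmer_index(records$sequence, ids = records$record_id, k = k)),
    class = "ref_index")
}

# Identities of one mate against prefiltered references.
# Returns data frame (record_id, identity) for identity >= min_hit_identity.
mate_hits <- function(seq, ref, params) {
  cand <- search_candidates(seq, ref$index, top_n = params$max_candidates)
  if (length(cand) == 0)
    return(data.frame(record_id = character(), identity = numeric(),
                      stringsAsFactors = FALSE))
  al <- .identity_many(toupper(seq), unname(ref$sequences[cand]))
  ids <- al[, "identity_pct"]
  floor_cols <- pmin(params$min_hit_overlap, nchar(seq),
                     nchar(unname(ref$sequences[cand])))
  keep <- ids >= params$min_hit_identity & al[, "aligned_cols"] >= floor_cols
  data.frame(record_id = cand[keep], identity = ids[keep],
             stringsAsFactors = FALSE)
}

# Deepest-rank consensus walk over retained-hit lineages. Agreement is on
# the full lineage prefix down to the rank under test, so homonymous names
# in different groups cannot pool. If two distinct prefixes both reach the
# fraction at a rank, that rank fails and the walk continues upward.
consensus_lineage <- function(lineages, fraction) {
  n <- length(lineages)
  if (n == 0) return(lineage())
  for (d in rev(seq_len(max(lengths(lineages))))) {
    keys <- vapply(lineages, function(l) {
      l <- as.character(l)
      if (length(l) >= d) paste(l[seq_len(d)], collapse = "\r") else NA_character_
    }, character(1))
    tab <- table(keys[!is.na(keys)])
    if (length(tab) == 0) next
    winners <- names(tab)[tab >= fraction * n]
    if (length(winners) == 1)
      return(lineage(strsplit(winners, "\r", fixed = TRUE)[[1]]))
    # 0 winners: no consensus here; >1: exact tie -> rank fails; walk up.
  }
  return(lineage())
}

assignment_result <- function(lineage, mode, best_avg_identity = NA_real_,
                              hits = character(), avg_identities = numeric()) {
  structure(list(lineage = lineage, mode = mode,
                 best_avg_identity_pct = best_avg_identity,
                 n_retained_hits = length(hits), hit_ids = hits,
                 hit_avg_identities = avg_identities),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment [%s]: %s (best avg %.2f%%, %d hits)>\n", x$mode,
              if (length(x$lineage)) format_lineage(x$lineage) else "<unassigned>",
              x$best_avg_identity_pct, x$n_retained_hits))
  invisible(x)
}

#' Dual-read consensus taxonomic assignment
#'
#' The central classification procedure for non-overlapping read pairs. Each
#' mate is queried independently against the reference set (the reverse mate
#' is reverse-complemented on entry); a reference *matches* a mate iff its
#' identity is at least `min_hit_identity`. Only references matching BOTH
#' mates are candidates; per candidate the forward and reverse identities
#' are averaged, candidates within `identity_window` points of the maximum
#' average are retained, and the assignment is made at the deepest rank
#' where a lineage prefix is shared by at least `consensus_fraction` of the
#' retained hits. If exactly one mate has matches, the procedure repeats
#' with that mate alone (`single_read` mode). When both mates have matches
#' but no reference matches both, the mates point at different taxa -- the
#' signature of an undetected chimera -- and the result is `unassigned`
#' rather than a one-mate guess. With no matches at all the result is
#' `unassigned`.
#'
#' @param fwd Forward sequence (plus strand).
#' @param rev Reverse mate as sequenced (minus strand); NA/empty to force
#'   single-read classification on the forward mate.
#' @param ref A [build_ref_index()] reference set.
#' @param params A [classifier_params()].
#' @return An `assignment_result` with `mode` one of `dual_read`,
#'   `single_read`, `unassigned`.
#' @export
dual_read_assign <- function(fwd, rev, ref, params = classifier_params()) {
  stopifnot(inherits(ref, "ref_index"))
  if (nrow(ref$records) == 0) stop("empty reference library")
  fh <- mate_hits(fwd, ref, params)
  rh <- if (!is.null(rev) && !is.na(rev) && nzchar(rev))
    mate_hits(revcomp(rev), ref, params)
  else data.frame(record_id = character(), identity = numeric())
  both <- intersect(fh$record_id, rh$record_id)
  if (length(both) > 0) {
    avg <- (fh$identity[match(both, fh$record_id)] +
              rh$identity[match(both, rh$record_id)]) / 2
    mode <- "dual_read"
  } else {
    # both mates with hits but disjoint reference sets: mate conflict
    # (undetected chimera signature) -> unassigned
    if (nrow(fh) > 0 && nrow(rh) > 0)
      return(assignment_result(lineage(), "unassigned"))
    if (nrow(fh) == 0 && nrow(rh) == 0)
      return(assignment_result(lineage(), "unassigned"))
    use <- if (nrow(fh) > 0) fh else rh
    both <- use$record_id
    avg <- use$identity
    mode <- "single_read"
  }
  retained <- avg >= max(avg) - params$identity_window
  hits <- both[retained]
  lin <- consensus_lineage(ref$lineages[hits], params$consensus_fraction)
  assignment_result(lin, mode, max(avg), hits, avg[retained])
}

#' Lowest-common-ancestor fallback assignment
#'
#' For clusters with no usable match in the primary COI library ("others"),
#' hits are gathered as in [dual_read_assign()] but against a secondary
#' (e.g. bacterial/contaminant) reference set; hits with average identity
#' within `lca_top_window` points of the maximum are retained and the
#' assignment is the longest lineage prefix common to all of them.
#'
#' @inheritParams dual_read_assign
#' @return An `assignment_result` with `mode` `lca_fallback` (or
#'   `unassigned` when there are no hits).
#' @export
lca_assign <- function(fwd, rev, ref, params = classifier_params()) {
  base <- dual_read_assign(fwd, rev, ref,
                           modifyList(params,
                                      list(identity_window = params$lca_top_window)))
  if (base$mode == "unassigned") return(base)
  lin <- lineage_common_prefix(ref$lineages[base$hit_ids])
  assignment_result(lin, "lca_fallback", base$best_avg_identity_pct,
                    base$hit_ids, base$hit_avg_identities)
}

#' Default MOTU category rules
#'
#' An ordered rule list mapping assigned lineages to ecological categories:
#' unassigned lineages stay `unassigned`; Bacteria are `putative_symbiont`;
#' insects in the host orders are `host`; insects in the parasitoid orders
#' are `parasitoid`; any other cellular life is `contaminant`.
#'
#' @param host_orders Orders whose members count as hosts (default
#'   Lepidoptera).
#' @param parasitoid_orders Orders whose members count as parasitoids
#'   (default Hymenoptera and Diptera).
#' @return List of `(predicate, category)` rules for [categorize_motu()].
#' @export
default_category_rules <- function(host_orders = "Lepidoptera",
                                   parasitoid_orders = c("Hymenoptera",
                                                         "Diptera")) {
  list(
    list(predicate = function(l) length(l) == 0, category = "unassigned"),
    list(predicate = function(l) l[1] == "Bacteria",
         category = "putative_symbiont"),
    list(predicate = function(l) any(l %in% host_orders) && "Insecta" %in% l,
         category = "host"),
    list(predicate = function(l) any(l %in% parasitoid_orders) && "Insecta" %in% l,
         category = "parasitoid"),
    list(predicate = function(l) TRUE, category = "contaminant"))
}

#' Categorize a MOTU from its assignment
#'
#' First matching rule wins.
#'
#' @param assignment An `assignment_result`.
#' @param rules Ordered rule list ([default_category_rules()]).
#' @return Category string.
#' @export
categorize_motu <- function(assignment, rules = default_category_rules()) {
  lin <- as.character(assignment$lineage)
  if (assignment$mode == "unassigned" || length(lin) == 0) return("unassigned")
  for (r in rules) if (isTRUE(r$predicate(lin))) return(r$category)
  "contaminant"
}

#' Standard-barcoding best-hit identification
#'
#' Sanger-style identification of a full-length query: the best hit by
#' identity gives the species when its divergence (100 - identity) is at
#' most `max_divergence_pct`; otherwise the deepest rank shared by all hits
#' within a `window`-point identity band of the best hit is returned, or
#' `unassigned` when there are no hits.
#'
#' @param query Full-length DNA string (>= 500 nt for barcode compliance;
#'   shorter queries are accepted with a warning).
#' @param ref A [build_ref_index()].
#' @param max_divergence_pct Species-call divergence ceiling (default 3).
#' @param window Identity band for the shared-rank fallback (default 5).
#' @param params A [classifier_params()] (prefilter settings only).
#' @return An `assignment_result` with mode `dual_read`-like semantics:
#'   `single_read` (best hit call) or `unassigned`.
#' @export
standard_barcode_identify <- function(query, ref, max_divergence_pct = 3.0,
                                      window = 5.0,
                                      params = classifier_params()) {
  if (nchar(query) < 500)
    warning("query shorter than 500 nt is not barcode compliant")
  cand <- search_candidates(query, ref$index, top_n = params$max_candidates)
  if (length(cand) == 0) return(assignment_result(lineage(), "unassigned"))
  al <- .identity_many(toupper(query), unname(ref$sequences[cand]))
  ids <- al[, "identity_pct"]
  floor_cols <- pmin(params$min_hit_overlap, nchar(query),
                     nchar(unname(ref$sequences[cand])))
  ok <- al[, "aligned_cols"] >= floor_cols
  cand <- cand[ok]; ids <- ids[ok]
  if (length(cand) == 0) return(assignment_result(lineage(), "unassigned"))
  ord <- order(-ids, cand, method = "radix")
  cand <- cand[ord]; ids <- ids[ord]
  if (100 - ids[1] <= max_divergence_pct)
    return(assignment_result(ref$lineages[[cand[1]]], "single_read", ids[1],
                             cand[1], ids[1]))
  keep <- ids >= ids[1] - window
  lin <- lineage_common_prefix(ref$lineages[cand[keep]])
  # beyond the divergence ceiling a species call is never made, even when a
  # single hit occupies the window
  if (length(lin) >= length(LINEAGE_RANKS))
    lin <- lineage(as.character(lin)[seq_len(length(LINEAGE_RANKS) - 1)])
  if (length(lin) == 0)
    return(assignment_result(lineage(), "unassigned", ids[1]))
  assignment_result(lin, "single_read", ids[1], cand[keep], ids[keep])
}
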