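#' Mock-community recovery scoring
#'
#' A specimen (individual) is recovered iff some MOTU representative aligns
#' to its Sanger barcode with identity >= `min_identity` over at least
#' `min_overlap` aligned columns; a taxon (BIN) is recovered iff any of its
#' specimens is. The overlap floor emulates the e-value criterion of a
#' blast-style search: at >= 97% identity over >= 100 nt the e-value
#' condition is always met for any realistic database, so overlap is the
#' binding constraint. Both the forward and (reverse-complemented) reverse
#' representatives are tried.
#'
#' @param motus A `motu_set` (or any data frame with `motu_id`,
#'   `centroid_fwd`, optional `centroid_rev`).
#' @param barcodes Data frame with `specimen_id`, `taxon_id`, `sequence`.
#' @param min_identity Identity threshold (default 97).
#' @param min_overlap Minimum aligned columns (default 100).
#' @return List of class `recovery_report`: `individuals` (per-specimen
#'   matched flag, best identity, matching motu), `taxa` (per-taxon matched
#'   flag), and fractions `individual_recovery` / `taxon_recovery`.
#' @export
match_recovery <- function(motus, barcodes, min_identity = 97.0,
                           min_overlap = 100) {
  reps <- if (inherits(motus, "motu_set")) motus$motus else motus
  stopifnot(all(c("specimen_id", "taxon_id", "sequence") %in% names(barcodes)))
  n_rep <- nrow(reps)
  ind <- data.frame(specimen_id = barcodes$specimen_id,
                    taxon_id = barcodes$taxon_id,
                    matched = FALSE, best_identity = NA_real_,
                    motu_id = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(barcodes))) {
    bc <- barcodes$sequence[i]
    best <- -Inf
    best_m <- NA_character_
    for (j in seq_len(n_rep)) {
      queries <- reps$centroid_fwd[j]
      if (!is.null(reps$centroid_rev) && !is.na(reps$centroid_rev[j]))
        queries <- c(queries, revcomp(reps$centroid_rev[j]))
      for (q in queries) {
        al <- .identity_core(toupper(q), toupper(bc))
        # identity is only comparable over a meaningful overlap
        if (al[["aligned_cols"]] >= min_overlap &&
            al[["identity_pct"]] > best) {
          best <- al[["identity_pct"]]
          best_m <- reps$motu_id[j]
        }
      }
    }
    ind$matched[i] <- is.finite(best) && best >= min_identity
    ind$best_identity[i] <- if (is.finite(best)) best else NA_real_
    ind$motu_id[i] <- best_m
  }
  taxa_ids <- unique(barcodes$taxon_id)
  taxa <- data.frame(taxon_id = taxa_ids,
                     matched = vapply(taxa_ids, function(t)
                       any(ind$matched[ind$taxon_id == t]), logical(1)),
                     stringsAsFactors = FALSE)
  structure(list(individuals = ind, taxa = taxa,
                 individual_recovery = mean(ind$matched),
                 taxon_recovery = mean(taxa$matched)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery: %d/%d individuals (%.1f%%), %d/%d taxa (%.1f%%)\n",
              sum(x$individuals$matched), nrow(x$individuals),
              100 * x$individual_recovery,
              sum(x$taxa$matched), nrow(x$taxa), 100 * x$taxon_recovery))
  invisible(x)
}

#' k-sample chi-square test of equal proportions
#'
#' The textbook test without continuity correction: with pooled proportion
#' `p = sum(successes) / sum(totals)`, the statistic is
#' `sum((O - E)^2 / E)` over the success and failure cells of every group,
#' with `k - 1` degrees of freedom and an upper-tail chi-square p-value.
#' (No correction is applied: the benchmark's printed statistics are only
#' reproduced without it.)
#'
#' @param successes,totals Integer vectors of equal length (>= 2 groups).
#' @return List of class `prop_test_result`: `chi2`, `df`, `p_value`.
#' @examples
#' equal_proportions_test(c(22, 22, 21), c(22, 22, 22)) # chi2 2.03, p 0.362
#' @export
equal_proportions_test <- function(successes, totals) {
  stopifnot(length(successes) == length(totals), length(successes) >= 2,
            all(successes >= 0), all(totals >= 1), all(successes <= totals))
  k <- length(successes)
  p_hat <- sum(successes) / sum(totals)
  if (p_hat == 0 || p_hat == 1) {
    chi2 <- 0
    p <- 1
  } else {
    e_succ <- totals * p_hat
    e_fail <- totals * (1 - p_hat)
    chi2 <- sum((successes - e_succ)^2 / e_succ +
                  ((totals - successes) - e_fail)^2 / e_fail)
    p <- pchisq(chi2, df = k - 1, lower.tail = FALSE)
  }
  structure(list(chi2 = chi2, df = k - 1, p_value = p),
            class = "prop_test_result")
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf("chi2 = %.2f, df = %d, P = %.3f\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Identification-success matrix across methods
#'
#' For each method and taxonomic level, an individual counts as a success
#' iff the method's assigned lineage names the *true* taxon at that level
#' (levels are evaluated independently; an empty assignment fails at every
#' level).
#'
#' @param assignments Data frame with `individual`, `method`, `lineage`
#'   (serialized assigned lineage, possibly empty).
#' @param truth Data frame with `individual`, `lineage` (serialized truth,
#'   populated to species).
#' @param levels Named integer vector mapping level name to lineage depth
#'   (default family/genus/species at schema depths 5/7/8).
#' @return List of class `identification_matrix`: `successes` and `pct`
#'   (method x level matrices) and `n` individuals.
#' @export
identification_matrix <- function(assignments, truth,
                                  levels = c(family = 5, genus = 7,
                                             species = 8)) {
  stopifnot(all(assignments$individual %in% truth$individual))
  methods <- unique(assignments$method)
  n <- length(unique(truth$individual))
  succ <- matrix(0L, nrow = length(methods), ncol = length(levels),
                 dimnames = list(methods, names(levels)))
  truth_lin <- lapply(truth$lineage, parse_lineage)
  names(truth_lin) <- truth$individual
  for (m in methods) {
    rows <- assignments[assignments$method == m, ]
    for (li in seq_along(levels)) {
      d <- levels[li]
      hits <- vapply(seq_len(nrow(rows)), function(i) {
        got <- parse_lineage(rows$lineage[i])
        want <- truth_lin[[rows$individual[i]]]
        length(got) >= d && length(want) >= d && got[d] == want[d]
      }, logical(1))
      succ[m, li] <- sum(hits)
    }
  }
  structure(list(successes = succ, pct = round(100 * succ / n, 1), n = n),
            class = "identification_matrix")
}

#' Compare identification methods with equal-proportions tests
#'
#' Runs [equal_proportions_test()] per taxonomic level across methods.
#'
#' @param successes Method x level integer matrix (as in
#'   [identification_matrix()]`$successes`, or built from the `table1`
#'   fixture).
#' @param n Individuals per method (scalar or per-method vector).
#' @return Data frame with one row per level: `level`, `chi2`, `df`,
#'   `p_value`.
#' @export
compare_methods <- function(successes, n) {
  totals <- rep(n, length.out = nrow(successes))
  out <- lapply(colnames(successes), function(lv) {
    t <- equal_proportions_test(successes[, lv], totals)
    data.frame(level = lv, chi2 = t$chi2, df = t$df, p_value = t$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' BIN-versus-morphospecies reference-library audit
#'
#' Aggregates per-group specimen records into per-guild totals and
#' BIN-weighted assignment percentages per rank. Printed per-group
#' percentages are rounded, so the aggregate first reconstructs the integer
#' number of assigned BINs per group (`round_half_up(n_bins * pct / 100)`)
#' and then reports `100 * sum(assigned) / sum(n_bins)` rounded half-up to
#' one decimal -- this reproduces the published sum rows exactly, which the
#' naive weighted mean of rounded percentages does not.
#'
#' @param records Data frame like the `table2` fixture
#'   ([load_fixture_tables()]).
#' @return List of class `library_summary`: per guild, `totals`
#'   (specimens, morphospecies, BINs), `pct_assigned` per rank, the
#'   reconstructed `n_assigned` counts, and `diversity_delta` (groups where
#'   BINs and morphospecies counts differ).
#' @export
library_completeness <- function(records) {
  ranks <- c("family", "subfamily", "genus", "species")
  stopifnot(all(c("guild", "n_specimens", "n_morphospecies", "n_bins",
                  paste0("pct_", ranks)) %in% names(records)))
  out <- list()
  for (g in unique(records$guild)) {
    r <- records[records$guild == g, ]
    assigned <- vapply(ranks, function(rk)
      sum(round_half_up(r$n_bins * r[[paste0("pct_", rk)]] / 100, 0)),
      numeric(1))
    out[[g]] <- list(
      totals = c(specimens = sum(r$n_specimens),
                 morphospecies = sum(r$n_morphospecies),
                 bins = sum(r$n_bins)),
      n_assigned = assigned,
      pct_assigned = round_half_up(100 * assigned / sum(r$n_bins), 1),
      diversity_delta = r[r$n_bins != r$n_morphospecies,
                          c("taxon_group", "n_morphospecies", "n_bins")])
  }
  structure(out, class = "library_summary")
}

#' @export
print.library_summary <- function(x, ...) {
  for (g in names(x)) {
    cat(sprintf("%s: %d specimens, %d morphospecies, %d BINs\n", g,
                x[[g]]$totals["specimens"], x[[g]]$totals["morphospecies"],
                x[[g]]$totals["bins"]))
    cat("  % BINs assigned:",
        paste(sprintf("%s %.1f", names(x[[g]]$pct_assigned),
                      x[[g]]$pct_assigned), collapse = ", "), "\n")
  }
  invisible(x)
}
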