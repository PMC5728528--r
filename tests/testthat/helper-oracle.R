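# Independent pure-R oracle for the semi-global aligner.
#
# Same scoring contract as the package kernel (+1 match, -1 mismatch, -2 per
# gap position, free terminal gaps, lexicographic tie rule: max score, then
# min aligned columns, then max matches) but implemented as a straightforward
# cell-by-cell R recurrence over (score, cols, matches) triples, written
# without reference to the C++ code.

iupac_mask_r <- c(A = 1, C = 2, G = 4, T = 8, U = 8, R = 5, Y = 10, S = 6,
                  W = 9, K = 12, M = 3, B = 14, D = 13, H = 11, V = 7, N = 15)

oracle_compat <- function(x, y) {
  bitwAnd(iupac_mask_r[[x]], iupac_mask_r[[y]]) != 0
}

oracle_better <- function(a, b) {
  if (a[1] != b[1]) return(a[1] > b[1])
  if (a[2] != b[2]) return(a[2] < b[2])
  a[3] > b[3]
}

# Returns list(identity, score, cols, matches)
oracle_align <- function(query, target) {
  qa <- strsplit(toupper(query), "")[[1]]
  tb <- strsplit(toupper(target), "")[[1]]
  n <- length(qa); m <- length(tb)
  S <- array(0, dim = c(n + 1, m + 1, 3))
  for (i in 1:n) for (j in 1:m) {
    hit <- oracle_compat(qa[i], tb[j])
    diag <- S[i, j, ] + c(if (hit) 1 else -1, 1, if (hit) 1 else 0)
    up <- S[i, j + 1, ] + c(-2, 1, 0)
    left <- S[i + 1, j, ] + c(-2, 1, 0)
    best <- diag
    if (oracle_better(up, best)) best <- up
    if (oracle_better(left, best)) best <- left
    S[i + 1, j + 1, ] <- best
  }
  best <- c(0, 0, 0)
  for (i in 0:n) if (oracle_better(S[i + 1, m + 1, ], best)) best <- S[i + 1, m + 1, ]
  for (j in 0:m) if (oracle_better(S[n + 1, j + 1, ], best)) best <- S[n + 1, j + 1, ]
  list(identity = if (best[2] > 0) 100 * best[3] / best[2] else 0,
       score = best[1], cols = best[2], matches = best[3])
}

# Connected components of the >= threshold identity graph (igraph-free
# union-find), used as the clustering count oracle. The same coverage floor
# as the clusterer applies: identity only counts over a meaningful overlap.
identity_components <- function(seqs, threshold, min_overlap = 100) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- align_identity(seqs[i], seqs[j])
    hit <- al$identity_pct >= threshold &&
      al$aligned_cols >= min(min_overlap, nchar(seqs[i]), nchar(seqs[j]))
    if (hit) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}
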