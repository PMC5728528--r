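#include <Rcpp.h>
#include <cctype>
#include <vector>
#include <string>
using namespace Rcpp;

// IUPAC nucleotide bit masks (A=1, C=2, G=4, T=8); two bases are compatible
// iff their masks intersect. U is folded into T.
static inline int iupac_mask(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 5;  // A/G
    case 'Y': return 10; // C/T
    case 'S': return 6;  // C/G
    case 'W': return 9;  // A/T
    case 'K': return 12; // G/T
    case 'M': return 3;  // A/C
    case 'B': return 14; // C/G/T
    case 'D': return 13; // A/G/T
    case 'H': return 11; // A/C/T
    case 'V': return 7;  // A/C/G
    case 'N': return 15;
    default:  return 0;
  }
}

static void encode(const std::string& s, std::vector<int>& out, const char* arg) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int m = iupac_mask(s[i]);
    if (m == 0)
      stop("non-IUPAC character '%c' at position %d of %s", s[i], (int)(i + 1), arg);
    out[i] = m;
  }
}

// Alignment objective under semi-global (free terminal gap) scoring:
// +1 match, -1 mismatch, -2 per gap position. Ties on the score are broken
// by a fixed additive lexicographic rule -- minimize aligned columns, then
// maximize matches -- so the reported identity is a well-defined function of
// the sequence pair, independent of traceback order.
struct Cell { int s; int c; int m; };

static inline bool better(const Cell& a, const Cell& b) {
  if (a.s != b.s) return a.s > b.s;
  if (a.c != b.c) return a.c < b.c;
  return a.m > b.m;
}

static const int GAP = -2, MISMATCH = -1, MATCH = 1;

// Identity-only DP with two rolling rows; returns (identity, score, cols, matches).
// [[Rcpp::export(name = ".identity_core")]]
NumericVector identity_core(std::string query, std::string target) {
  std::vector<int> a, b;
  encode(query, a, "query");
  encode(target, b, "target");
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<Cell> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = {0, 0, 0};
  Cell best = prev[m]; // endpoint (0, m): empty alignment on last column
  for (int i = 1; i <= n; ++i) {
    cur[0] = {0, 0, 0};
    for (int j = 1; j <= m; ++j) {
      bool hit = (a[i - 1] & b[j - 1]) != 0;
      Cell d = {prev[j - 1].s + (hit ? MATCH : MISMATCH), prev[j - 1].c + 1,
                prev[j - 1].m + (hit ? 1 : 0)};
      Cell u = {prev[j].s + GAP, prev[j].c + 1, prev[j].m};
      Cell l = {cur[j - 1].s + GAP, cur[j - 1].c + 1, cur[j - 1].m};
      Cell z = d;
      if (better(u, z)) z = u;
      if (better(l, z)) z = l;
      cur[j] = z;
    }
    if (better(cur[m], best)) best = cur[m]; // last column endpoints
    std::swap(prev, cur);
  }
  for (int j = 0; j <= m; ++j)
    if (better(prev[j], best)) best = prev[j]; // last row endpoints
  double ident = best.c > 0 ? 100.0 * best.m / best.c : 0.0;
  return NumericVector::create(_["identity_pct"] = ident, _["score"] = best.s,
                               _["aligned_cols"] = best.c, _["matches"] = best.m);
}

// [[Rcpp::export(name = ".identity_many")]]
NumericMatrix identity_many(std::string query, CharacterVector targets) {
  NumericMatrix out(targets.size(), 4);
  colnames(out) = CharacterVector::create("identity_pct", "score",
                                          "aligned_cols", "matches");
  for (R_xlen_t k = 0; k < targets.size(); ++k) {
    NumericVector r = identity_core(query, as<std::string>(targets[k]));
    for (int j = 0; j < 4; ++j) out(k, j) = r[j];
  }
  return out;
}

// Full DP with traceback: returns spans, per-column ops and match flags.
// [[Rcpp::export(name = ".align_core")]]
List align_core(std::string query, std::string target) {
  std::vector<int> a, b;
  encode(query, a, "query");
  encode(target, b, "target");
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<Cell> S((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> dir((size_t)(n + 1) * (m + 1), 0); // 0=stop,1=diag,2=up,3=left
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) S[at(0, j)] = {0, 0, 0};
  for (int i = 0; i <= n; ++i) S[at(i, 0)] = {0, 0, 0};
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      bool hit = (a[i - 1] & b[j - 1]) != 0;
      const Cell& pd = S[at(i - 1, j - 1)];
      const Cell& pu = S[at(i - 1, j)];
      const Cell& pl = S[at(i, j - 1)];
      Cell d = {pd.s + (hit ? MATCH : MISMATCH), pd.c + 1, pd.m + (hit ? 1 : 0)};
      Cell u = {pu.s + GAP, pu.c + 1, pu.m};
      Cell l = {pl.s + GAP, pl.c + 1, pl.m};
      Cell z = d;
      unsigned char dz = 1;
      if (better(u, z)) { z = u; dz = 2; }
      if (better(l, z)) { z = l; dz = 3; }
      S[at(i, j)] = z;
      dir[at(i, j)] = dz;
    }
  }
  // Endpoint: best over last column (scanned top to bottom) then last row
  // (left to right); strict improvement keeps the first optimum.
  int ei = 0, ej = m;
  Cell best = S[at(0, m)];
  for (int i = 1; i <= n; ++i)
    if (better(S[at(i, m)], best)) { best = S[at(i, m)]; ei = i; ej = m; }
  for (int j = 0; j <= m; ++j)
    if (better(S[at(n, j)], best)) { best = S[at(n, j)]; ei = n; ej = j; }
  // Traceback to the first row/column.
  std::vector<int> ops;
  std::vector<int> mv;
  int i = ei, j = ej;
  while (i > 0 && j > 0) {
    unsigned char dz = dir[at(i, j)];
    if (dz == 1) {
      ops.push_back(0);
      mv.push_back((a[i - 1] & b[j - 1]) != 0 ? 1 : 0);
      --i; --j;
    } else if (dz == 2) {
      ops.push_back(1); mv.push_back(0); --i;
    } else {
      ops.push_back(2); mv.push_back(0); --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(mv.begin(), mv.end());
  double ident = best.c > 0 ? 100.0 * best.m / best.c : 0.0;
  return List::create(
      _["identity_pct"] = ident, _["score"] = best.s,
      _["aligned_cols"] = best.c, _["matches"] = best.m,
      _["query_span"] = IntegerVector::create(i, ei),
      _["target_span"] = IntegerVector::create(j, ej),
      _["ops"] = IntegerVector(ops.begin(), ops.end()),
      _["match_vector"] = LogicalVector(mv.begin(), mv.end()));
}
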