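#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdlib>
using namespace Rcpp;

// Ends-free ("overlap") global alignment restricted to a diagonal band.
// Terminal overhangs are free and excluded from the reported columns, so
// identity is measured on the aligned region only; internal gaps count as
// columns. Scores: match +2, mismatch -3, gap -5 (linear). The band is the
// maximum |i - j| explored; pairs whose optimal path drifts outside the band
// get a lower-bound identity, which is all a fixed-threshold clusterer needs.
static void overlap_stats(const std::string& a, const std::string& b,
                          int band, int& matches, int& columns) {
  const int n = (int) a.size(), m = (int) b.size();
  matches = 0; columns = 0;
  if (n == 0 || m == 0) return;
  const int MATCH = 2, MISMATCH = -3, GAP = -5;
  const int NEG = -1000000000;
  if (band < 1) band = 1;
  std::vector<int> S((size_t)(n + 1) * (m + 1), NEG);
  std::vector<unsigned char> D((size_t)(n + 1) * (m + 1), 0);
  const size_t W = (size_t) m + 1;
  for (int j = 0; j <= m; ++j) S[j] = 0;
  for (int i = 0; i <= n; ++i) S[(size_t) i * W] = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = i - band; if (jlo < 1) jlo = 1;
    int jhi = i + band; if (jhi > m) jhi = m;
    const size_t row = (size_t) i * W, prev = row - W;
    for (int j = jlo; j <= jhi; ++j) {
      int best = NEG; unsigned char dir = 0;
      int sd = S[prev + j - 1];
      if (sd > NEG) {
        int sc = sd + (a[i - 1] == b[j - 1] ? MATCH : MISMATCH);
        if (sc > best) { best = sc; dir = 1; }
      }
      int su = S[prev + j];
      if (su > NEG && su + GAP > best) { best = su + GAP; dir = 2; }
      int sl = S[row + j - 1];
      if (sl > NEG && sl + GAP > best) { best = sl + GAP; dir = 3; }
      S[row + j] = best; D[row + j] = dir;
    }
  }
  // ends-free: best cell over last row and last column
  int bi = 0, bj = 0, bscore = NEG;
  for (int j = 0; j <= m; ++j)
    if (S[(size_t) n * W + j] > bscore) { bscore = S[(size_t) n * W + j]; bi = n; bj = j; }
  for (int i = 0; i <= n; ++i)
    if (S[(size_t) i * W + m] > bscore) { bscore = S[(size_t) i * W + m]; bi = i; bj = m; }
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    unsigned char d = D[(size_t) i * W + j];
    if (d == 1) { if (a[i - 1] == b[j - 1]) ++matches; --i; --j; }
    else if (d == 2) { --i; }
    else if (d == 3) { --j; }
    else break;
    ++columns;
  }
}

// [[Rcpp::export]]
IntegerVector overlap_align_stats_cpp(std::string a, std::string b, int band) {
  int matches = 0, columns = 0;
  overlap_stats(a, b, band, matches, columns);
  return IntegerVector::create(_["matches"] = matches, _["columns"] = columns);
}

// [[Rcpp::export]]
NumericVector overlap_identity_cpp(CharacterVector queries, std::string ref,
                                   int band, int definition) {
  // definition: 1 = matches / alignment columns, 2 = matches / shorter length
  const int nq = queries.size();
  NumericVector out(nq);
  const int m = (int) ref.size();
  for (int k = 0; k < nq; ++k) {
    std::string q = as<std::string>(queries[k]);
    int matches = 0, columns = 0;
    overlap_stats(q, ref, band, matches, columns);
    double denom;
    if (definition == 1) denom = (double) columns;
    else denom = (double) std::min((int) q.size(), m);
    out[k] = denom > 0 ? matches / denom : 0.0;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector prefix_mismatch_cpp(CharacterVector queries, std::string ref) {
  // Hamming mismatches over the shared-length prefix (no indel tolerance);
  // used as a fast exact shortcut for substitution-only reads.
  const int nq = queries.size();
  IntegerVector out(nq);
  for (int k = 0; k < nq; ++k) {
    std::string q = as<std::string>(queries[k]);
    size_t L = std::min(q.size(), ref.size());
    int mm = 0;
    for (size_t i = 0; i < L; ++i) if (q[i] != ref[i]) ++mm;
    out[k] = mm;
  }
  return out;
}
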