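#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty and full traceback.
// Tie-break among equal-scoring end cells: smallest subject end, then smallest
// query end; traceback prefers diagonal over up (query gap) over left, which
// makes the reported coordinates deterministic.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string s,
                  double match, double mismatch, double gap) {
  const int m = (int) q.size(), n = (int) s.size();
  std::vector<double> prev(n + 1, 0.0), cur(n + 1, 0.0);
  // traceback codes: 0 stop, 1 diag, 2 up (gap in subject), 3 left (gap in query)
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = 0.0;
    const char qc = q[(size_t)i - 1];
    for (int j = 1; j <= n; ++j) {
      double diag = prev[j - 1] + (qc == s[(size_t)j - 1] ? match : mismatch);
      double up   = prev[j] + gap;
      double left = cur[j - 1] + gap;
      double v = diag; unsigned char t = 1;
      if (up > v)   { v = up;   t = 2; }
      if (left > v) { v = left; t = 3; }
      if (v <= 0.0) { v = 0.0;  t = 0; }
      cur[j] = v;
      tb[(size_t)i * (n + 1) + j] = t;
      if (v > best || (v == best && (j < bj || (j == bj && i < bi)))) {
        if (v > 0.0) { best = v; bi = i; bj = j; }
      }
    }
    std::swap(prev, cur);
  }
  if (best <= 0.0) return List::create(Named("score") = 0.0);
  // traceback
  int i = bi, j = bj;
  int matches = 0, mismatches = 0, gaps = 0, gap_opens = 0, alen = 0;
  int last_gap = 0; // 0 none, 2 up-run, 3 left-run
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * (n + 1) + j];
    if (t == 0) break;
    if (t == 1) {
      if (q[(size_t)i - 1] == s[(size_t)j - 1]) ++matches; else ++mismatches;
      --i; --j; ++alen; last_gap = 0;
    } else if (t == 2) {
      ++gaps; if (last_gap != 2) ++gap_opens;
      --i; ++alen; last_gap = 2;
    } else {
      ++gaps; if (last_gap != 3) ++gap_opens;
      --j; ++alen; last_gap = 3;
    }
  }
  return List::create(
    Named("score") = best,
    Named("q_start") = i + 1, Named("q_end") = bi,
    Named("s_start") = j + 1, Named("s_end") = bj,
    Named("matches") = matches, Named("mismatches") = mismatches,
    Named("gaps") = gaps, Named("gap_opens") = gap_opens,
    Named("aln_len") = alen);
}

// Simulate a length-n sequence from an order-2 Markov chain over ACGT.
// trans: 16 x 4 row-stochastic matrix, row index 4*b1 + b2 (0-based A,C,G,T)
// for context (b1, b2); init: probabilities of the first two bases' 16 states.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".markov_gen_cpp")]]
std::string markov_gen_cpp(int n, NumericMatrix trans, NumericVector init) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  if (n <= 0) return std::string();
  std::string out((size_t)n, 'A');
  // cumulative rows
  std::vector<double> cum(16 * 4);
  for (int r = 0; r < 16; ++r) {
    double acc = 0.0;
    for (int c = 0; c < 4; ++c) { acc += trans(r, c); cum[(size_t)r * 4 + c] = acc; }
  }
  // initial two bases from joint init distribution
  std::vector<double> ic(16);
  double acc = 0.0;
  for (int k = 0; k < 16; ++k) { acc += init[k]; ic[(size_t)k] = acc; }
  double u = unif_rand() * acc;
  int st = 0; while (st < 15 && ic[(size_t)st] < u) ++st;
  int b1 = st / 4, b2 = st % 4;
  out[0] = B[b1];
  if (n == 1) return out;
  out[1] = B[b2];
  for (int i = 2; i < n; ++i) {
    int ctx = 4 * b1 + b2;
    double uu = unif_rand() * cum[(size_t)ctx * 4 + 3];
    int b = 0; while (b < 3 && cum[(size_t)ctx * 4 + b] < uu) ++b;
    out[(size_t)i] = B[b];
    b1 = b2; b2 = b;
  }
  return out;
}
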