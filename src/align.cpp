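#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with a linear gap model.
// Traceback preference at ties: diagonal, then up (gap in b), then left
// (gap in a) -- this fixes a single optimal alignment deterministically.
//
// Returns the aligned column maps (0 = gap), the optimal score, the
// identity (identical columns / length of the shorter sequence) and the
// coverage of each sequence (residues inside the mutually aligned span /
// sequence length; terminal overhangs do not count as covered).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = (int)a.size(), m = (int)b.size();
  NumericMatrix S(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) S(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) S(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double best = S(i - 1, j - 1) + sub;
      best = std::max(best, S(i - 1, j) + gap);
      best = std::max(best, S(i, j - 1) + gap);
      S(i, j) = best;
    }
  }

  std::vector<int> ai, bi;
  ai.reserve(n + m); bi.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (S(i, j) == S(i - 1, j - 1) + sub) {
        ai.push_back(i); bi.push_back(j); --i; --j; continue;
      }
    }
    if (i > 0 && S(i, j) == S(i - 1, j) + gap) {
      ai.push_back(i); bi.push_back(0); --i; continue;
    }
    ai.push_back(0); bi.push_back(j); --j;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  const int L = (int)ai.size();
  int n_ident = 0;
  int first_a = -1, last_a = -1, first_b = -1, last_b = -1;
  for (int k = 0; k < L; ++k) {
    if (ai[k] > 0) { if (first_a < 0) first_a = k; last_a = k; }
    if (bi[k] > 0) { if (first_b < 0) first_b = k; last_b = k; }
    if (ai[k] > 0 && bi[k] > 0 && a[ai[k] - 1] == b[bi[k] - 1]) ++n_ident;
  }
  int start = std::max(first_a, first_b);
  int end = std::min(last_a, last_b);
  int span_a = 0, span_b = 0;
  for (int k = start; k <= end && start >= 0; ++k) {
    if (ai[k] > 0) ++span_a;
    if (bi[k] > 0) ++span_b;
  }
  double shorter = (double)std::min(n, m);

  return List::create(
    _["score"] = S(n, m),
    _["identity"] = shorter > 0 ? n_ident / shorter : 0.0,
    _["cov_a"] = n > 0 ? (double)span_a / n : 0.0,
    _["cov_b"] = m > 0 ? (double)span_b / m : 0.0,
    _["a_pos"] = IntegerVector(ai.begin(), ai.end()),
    _["b_pos"] = IntegerVector(bi.begin(), bi.end()));
}
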