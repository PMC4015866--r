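#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Pair weights: G:C 3, A:U 2, G:U 1 (DNA alphabet, T == U). 0 = not pairable.
static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// Weighted base-pair maximization (Nussinov-style) over nested structures,
// minimum hairpin loop 3 nt. `mask` marks 1-based positions forced unpaired.
// Deterministic traceback: unpaired-j branch preferred on ties, then the
// smallest pairing partner k.
// [[Rcpp::export(name = ".fold_cpp")]]
List fold_cpp(std::string seq, IntegerVector mask) {
  const int n = (int) seq.size();
  const int minloop = 3;
  std::vector<bool> banned(n, false);
  for (int m = 0; m < mask.size(); ++m) {
    int p = mask[m];
    if (p >= 1 && p <= n) banned[p - 1] = true;
  }
  if (n == 0) return List::create(_["structure"] = "", _["score"] = 0.0);

  // dp is (n x n), row-major, dp[i*n+j] for i <= j
  std::vector<int> dp((size_t) n * n, 0);
  for (int len = minloop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = dp[(size_t) i * n + (j - 1)]; // j unpaired
      if (!banned[j]) {
        for (int k = i; k <= j - minloop - 1; ++k) {
          if (banned[k]) continue;
          int w = pair_weight(seq[k], seq[j]);
          if (w == 0) continue;
          int left = (k > i) ? dp[(size_t) i * n + (k - 1)] : 0;
          int inner = (k + 1 <= j - 1) ? dp[(size_t)(k + 1) * n + (j - 1)] : 0;
          int cand = left + w + inner;
          if (cand > best) best = cand;
        }
      }
      dp[(size_t) i * n + j] = best;
    }
  }

  std::string db(n, '.');
  // iterative traceback over interval stack
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < minloop + 1) continue;
    int cur = dp[(size_t) i * n + j];
    if (cur == dp[(size_t) i * n + (j - 1)]) { // j unpaired branch wins ties
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    bool done = false;
    if (!banned[j]) {
      for (int k = i; k <= j - minloop - 1 && !done; ++k) {
        if (banned[k]) continue;
        int w = pair_weight(seq[k], seq[j]);
        if (w == 0) continue;
        int left = (k > i) ? dp[(size_t) i * n + (k - 1)] : 0;
        int inner = (k + 1 <= j - 1) ? dp[(size_t)(k + 1) * n + (j - 1)] : 0;
        if (left + w + inner == cur) {
          db[k] = '(';
          db[j] = ')';
          if (k > i) stack.push_back(std::make_pair(i, k - 1));
          if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
          done = true;
        }
      }
    }
    if (!done) stack.push_back(std::make_pair(i, j - 1));
  }

  double score = -(double) dp[(size_t) 0 * n + (n - 1)];
  return List::create(_["structure"] = db, _["score"] = score);
}
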