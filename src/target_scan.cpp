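#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline bool wc_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G');
}
static inline bool gu_pair(char a, char b) {
  return (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Penalty-minimizing global duplex alignment of a miRNA against a site,
// <= max_gaps indels. `t` is the site read 3'->5' so t[j] aligns m[j] in
// the duplex. Penalties: match 0, G:U wobble, mismatch, gap; doubled at
// miRNA positions core_lo..core_hi. Returns best total penalty.
static double duplex_penalty(const std::string &m, const std::string &t,
                             double w_gu, double w_mm, double w_gap,
                             int core_lo, int core_hi, double core_mult,
                             int max_gaps) {
  const int n = (int) m.size(), L = (int) t.size();
  const double INF = 1e18;
  // D[g][i][j]
  std::vector<double> D((size_t)(max_gaps + 1) * (n + 1) * (L + 1), INF);
  auto idx = [&](int g, int i, int j) {
    return ((size_t) g * (n + 1) + i) * (L + 1) + j;
  };
  D[idx(0, 0, 0)] = 0.0;
  for (int g = 0; g <= max_gaps; ++g) {
    for (int i = 0; i <= n; ++i) {
      for (int j = 0; j <= L; ++j) {
        double cur = D[idx(g, i, j)];
        if (cur >= INF) continue;
        if (i < n && j < L) {
          char a = m[i], b = t[j];
          double c = wc_pair(a, b) ? 0.0 : (gu_pair(a, b) ? w_gu : w_mm);
          int pos = i + 1;
          if (pos >= core_lo && pos <= core_hi) c *= core_mult;
          double &d = D[idx(g, i + 1, j + 1)];
          if (cur + c < d) d = cur + c;
        }
        if (g < max_gaps) {
          if (i < n) { // miRNA base unpaired opposite a gap
            int pos = i + 1;
            double c = w_gap;
            if (pos >= core_lo && pos <= core_hi) c *= core_mult;
            double &d = D[idx(g + 1, i + 1, j)];
            if (cur + c < d) d = cur + c;
          }
          if (j < L) { // site base bulged out
            int pos = std::min(i + 1, n);
            double c = w_gap;
            if (pos >= core_lo && pos <= core_hi) c *= core_mult;
            double &d = D[idx(g + 1, i, j + 1)];
            if (cur + c < d) d = cur + c;
          }
        }
      }
    }
  }
  double best = INF;
  for (int g = 0; g <= max_gaps; ++g) best = std::min(best, D[idx(g, n, L)]);
  return best;
}

// Scan every start position of a transcript for duplex sites of a miRNA.
// Site lengths n-1..n+1 (one allowed indel). Returns all windows with
// penalty <= max_expectation: start, end (1-based on transcript), penalty.
// [[Rcpp::export(name = ".scan_transcript_cpp")]]
DataFrame scan_transcript_cpp(std::string mirna, std::string transcript,
                              double max_expectation,
                              double w_gu, double w_mm, double w_gap,
                              int core_lo, int core_hi, double core_mult,
                              int max_gaps) {
  const int n = (int) mirna.size();
  const int T = (int) transcript.size();
  std::vector<int> starts, ends;
  std::vector<double> pens;
  for (int s = 0; s < T; ++s) {
    for (int L = n - max_gaps; L <= n + max_gaps; ++L) {
      if (L < 1 || s + L > T) continue;
      // site read 3'->5': reverse of transcript[s..s+L-1], complemented
      // pairing is checked directly (m vs complement), so build the
      // reversed-complement-free representation: t[j] = complement of
      // transcript[s+L-1-j] would pair via identity; instead keep the
      // transcript base and test complementarity in wc_pair/gu_pair.
      std::string t(L, 'N');
      for (int j = 0; j < L; ++j) t[j] = transcript[s + L - 1 - j];
      double p = duplex_penalty(mirna, t, w_gu, w_mm, w_gap,
                                core_lo, core_hi, core_mult, max_gaps);
      if (p <= max_expectation) {
        starts.push_back(s + 1);
        ends.push_back(s + L);
        pens.push_back(p);
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["expectation"] = pens);
}
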