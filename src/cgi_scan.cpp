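#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// For each window start i (0-based), the largest end j (0-based exclusive)
// such that window [i, j) of length >= min_length satisfies the island
// criteria: GC fraction >= min_gc, observed/expected CpG > min_oe
// (expected = #C * #G / length, undefined counts as fail), and N content
// <= max_n_fraction of the window.  Returns -1 where no window qualifies.
// Windows starting at the same base are nested, so their union is [i, max j):
// unioning these intervals over all starts reproduces the union of every
// qualifying window.
// [[Rcpp::export]]
IntegerVector cgi_max_end_cpp(std::string seq, int min_length, double min_gc,
                              double min_oe, double max_n_fraction) {
  const int n = (int)seq.size();
  std::vector<int> C(n + 1, 0), G(n + 1, 0), N(n + 1, 0), CG(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    C[i + 1] = C[i] + (seq[i] == 'C');
    G[i + 1] = G[i] + (seq[i] == 'G');
    N[i + 1] = N[i] + (seq[i] == 'N');
    CG[i + 1] = CG[i] + (i + 1 < n && seq[i] == 'C' && seq[i + 1] == 'G');
  }
  IntegerVector out(n, -1);
  for (int i = 0; i + min_length <= n; ++i) {
    int best = -1;
    for (int j = i + min_length; j <= n; ++j) {
      const int len = j - i;
      const int nn = N[j] - N[i];
      if (nn > max_n_fraction * len) {
        if (max_n_fraction == 0.0) break; // N count only grows with j
        continue;
      }
      const int c = C[j] - C[i], g = G[j] - G[i];
      // evaluation order fixed to (c+g)/len and (c*g)/len so boundary
      // windows resolve identically here and in the R-level oracles
      if ((double)(c + g) / len < min_gc) continue;
      const double expv = (double)c * g / len;
      if (expv <= 0.0) continue;
      const int obs = CG[j - 1] - CG[i]; // CG starts fully inside [i, j)
      if ((double)obs > min_oe * expv) best = j;
    }
    out[i] = best;
  }
  return out;
}
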