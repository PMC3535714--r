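#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Semi-global ("glocal") alignment: the query is aligned end to end, the
// target contributes a free substring — leading and trailing target bases
// cost nothing and are not alignment columns.  Affine gaps and 'N' handling
// as in the local aligner: a gap of length L costs
// gap_open + (L - 1) * gap_extend, 'N' is a universal mismatch.  This is
// the natural model for locating where a whole element sits inside a long
// promoter region: internal gaps are paid for, so for a substitution-only
// homolog the optimum is the ungapped diagonal through the planted copy.
// Among equal-scoring optima the smallest target end is chosen, then path
// ties prefer aligned pairs over gaps, so the result is deterministic.
//
// States: M = q[i] vs t[j]; X = q[i] vs gap; Y = gap vs t[j] (internal only).
// [[Rcpp::export]]
List glocal_align_cpp(std::string query, std::string target, double match,
                      double mismatch, double gap_open, double gap_extend) {
  const int n = (int)query.size(), m = (int)target.size();
  if (n == 0 || m == 0) stop("query and target must be non-empty");
  const double NEG = -1e18;
  const size_t W = (size_t)(m + 1), sz = (size_t)(n + 1) * W;
  std::vector<double> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  std::vector<uint8_t> pM(sz, 0), pX(sz, 0), pY(sz, 0);
  // free start anywhere along the target before any query base is consumed
  for (int j = 0; j <= m; ++j) M[(size_t)j] = 0.0;
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    const char qc = query[i - 1];
    { // j = 0 column: only X (query against gap) is possible
      const double xm = M[prow] + gap_open;
      const double xx = X[prow] + gap_extend;
      if (xm >= xx) { X[row] = xm; pX[row] = 1; }
      else          { X[row] = xx; pX[row] = 2; }
      Y[row] = NEG;
      M[row] = NEG;
    }
    for (int j = 1; j <= m; ++j) {
      {
        const double xm = M[prow + j] + gap_open;
        const double xx = X[prow + j] + gap_extend;
        const double xy = Y[prow + j] + gap_open;
        if (xm >= xx && xm >= xy) { X[row + j] = xm; pX[row + j] = 1; }
        else if (xx >= xy)        { X[row + j] = xx; pX[row + j] = 2; }
        else                      { X[row + j] = xy; pX[row + j] = 3; }
      }
      {
        const double ym = M[row + j - 1] + gap_open;
        const double yx = X[row + j - 1] + gap_open;
        const double yy = Y[row + j - 1] + gap_extend;
        if (ym >= yy && ym >= yx) { Y[row + j] = ym; pY[row + j] = 1; }
        else if (yx >= yy)        { Y[row + j] = yx; pY[row + j] = 2; }
        else                      { Y[row + j] = yy; pY[row + j] = 3; }
      }
      {
        const char tc = target[j - 1];
        const double s = (qc == 'N' || tc == 'N') ? mismatch
                         : (qc == tc ? match : mismatch);
        double prev = M[prow + j - 1];
        uint8_t p = 1;
        if (X[prow + j - 1] > prev) { prev = X[prow + j - 1]; p = 2; }
        if (Y[prow + j - 1] > prev) { prev = Y[prow + j - 1]; p = 3; }
        M[row + j] = s + prev;
        pM[row + j] = p;
      }
    }
  }

  // free end: best cell in the last query row, smallest target end first;
  // the alignment may end on an aligned pair or a query-vs-gap column
  double best = NEG;
  int bj = -1, bstate = 1;
  const size_t lrow = (size_t)n * W;
  for (int j = 0; j <= m; ++j) {
    if (M[lrow + j] > best) { best = M[lrow + j]; bj = j; bstate = 1; }
    if (X[lrow + j] > best) { best = X[lrow + j]; bj = j; bstate = 2; }
  }

  int i = n, j = bj, state = bstate, ncol = 0, nid = 0;
  const int t_end = bj;
  while (i > 0) {
    const size_t k = (size_t)i * W + (size_t)j;
    if (state == 1) {
      ++ncol;
      if (query[i - 1] == target[j - 1] && query[i - 1] != 'N') ++nid;
      state = pM[k];
      --i; --j;
    } else if (state == 2) {
      ++ncol;
      state = pX[k];
      --i;
    } else {
      ++ncol;
      state = pY[k];
      --j;
    }
  }
  return List::create(
    _["score"] = best, _["t_start"] = j, _["t_end"] = t_end,
    _["n_columns"] = ncol, _["n_identical"] = nid);
}
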