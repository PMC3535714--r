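#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Affine-gap Smith-Waterman local alignment.
//
// A gap of length L costs gap_open + (L - 1) * gap_extend (both negative).
// 'N' scores `mismatch` against everything, including another 'N'.
// Among equal-scoring optima the alignment with the smallest target start,
// then the smallest target end, is returned; remaining path ties are broken
// by a fixed state preference (diagonal, then gap-in-target, then
// gap-in-query, then fresh start) so the result is deterministic.
//
// States: M = q[i] aligned to t[j]; X = q[i] against a gap (gap in target);
// Y = t[j] against a gap (gap in query).

static inline double subscore(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string target, double match,
                  double mismatch, double gap_open, double gap_extend) {
  const int n = (int)query.size(), m = (int)target.size();
  if (n == 0 || m == 0) stop("query and target must be non-empty");
  const double NEG = -1e18;
  const size_t sz = (size_t)(n + 1) * (size_t)(m + 1);
  std::vector<double> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  // predecessor codes: 0 = fresh start, 1 = M, 2 = X, 3 = Y
  std::vector<uint8_t> pM(sz, 0), pX(sz, 0), pY(sz, 0);
  const size_t W = (size_t)(m + 1);
  double best = 0.0;

  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      // X: consume q[i-1] against a gap
      {
        const double xm = M[prow + j] + gap_open;
        const double xx = X[prow + j] + gap_extend;
        if (xm >= xx) { X[row + j] = xm; pX[row + j] = 1; }
        else          { X[row + j] = xx; pX[row + j] = 2; }
      }
      // Y: consume t[j-1] against a gap
      {
        const double ym = M[row + j - 1] + gap_open;
        const double yy = Y[row + j - 1] + gap_extend;
        if (ym >= yy) { Y[row + j] = ym; pY[row + j] = 1; }
        else          { Y[row + j] = yy; pY[row + j] = 3; }
      }
      // M: align q[i-1] with t[j-1]
      {
        const double s = subscore(query[i - 1], target[j - 1], match, mismatch);
        double prev = M[prow + j - 1];
        uint8_t p = 1;
        if (X[prow + j - 1] > prev) { prev = X[prow + j - 1]; p = 2; }
        if (Y[prow + j - 1] > prev) { prev = Y[prow + j - 1]; p = 3; }
        if (0.0 >= prev) { prev = 0.0; p = 0; }
        M[row + j] = s + prev;
        pM[row + j] = p;
        if (M[row + j] > best) best = M[row + j];
      }
    }
  }

  if (best <= 0.0) {
    return List::create(
      _["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
      _["t_start"] = 0, _["t_end"] = 0, _["n_columns"] = 0,
      _["n_identical"] = 0, _["aligned_query"] = "", _["aligned_target"] = "");
  }

  // Trace an alignment back from M cell (i, j); returns starts (0-based).
  auto trace = [&](int i, int j, std::string *aq, std::string *at,
                   int *ncol, int *nid) {
    int state = 1; // start in M: the optimum always ends on an aligned pair
    while (true) {
      const size_t k = (size_t)i * W + (size_t)j;
      if (state == 1) {
        if (aq) {
          aq->push_back(query[i - 1]);
          at->push_back(target[j - 1]);
          ++*ncol;
          if (query[i - 1] == target[j - 1] && query[i - 1] != 'N') ++*nid;
        }
        const uint8_t p = pM[k];
        --i; --j;
        if (p == 0) break;
        state = p;
      } else if (state == 2) {
        if (aq) { aq->push_back(query[i - 1]); at->push_back('-'); ++*ncol; }
        const uint8_t p = pX[k];
        --i;
        state = p;
      } else {
        if (aq) { aq->push_back('-'); at->push_back(target[j - 1]); ++*ncol; }
        const uint8_t p = pY[k];
        --j;
        state = p;
      }
    }
    return std::make_pair(i, j); // (q_start, t_start), 0-based
  };

  // Candidate optima, resolved to (t_start, t_end, q cell) for tie-breaking.
  int best_i = -1, best_j = -1, best_ts = -1, best_te = -1;
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * W;
    for (int j = 1; j <= m; ++j) {
      if (M[row + j] == best) {
        auto st = trace(i, j, nullptr, nullptr, nullptr, nullptr);
        const int ts = st.second, te = j;
        if (best_i < 0 || ts < best_ts || (ts == best_ts && te < best_te)) {
          best_i = i; best_j = j; best_ts = ts; best_te = te;
        }
      }
    }
  }

  std::string aq, at;
  int ncol = 0, nid = 0;
  auto st = trace(best_i, best_j, &aq, &at, &ncol, &nid);
  std::reverse(aq.begin(), aq.end());
  std::reverse(at.begin(), at.end());

  return List::create(
    _["score"] = best,
    _["q_start"] = st.first, _["q_end"] = best_i,
    _["t_start"] = st.second, _["t_end"] = best_j,
    _["n_columns"] = ncol, _["n_identical"] = nid,
    _["aligned_query"] = aq, _["aligned_target"] = at);
}
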