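#include <Rcpp.h>
using namespace Rcpp;

// Maximum-total-weight strictly monotone matching over a similarity matrix.
// Pairs (i, j) must be strictly increasing in both indices; only entries
// with S(i,j) >= s_min are eligible, and when forbid_self is set the
// diagonal i == j is excluded. Zero gap penalty. Traceback is deterministic:
// at a tie the pair is taken in preference to skipping a row or column.
// [[Rcpp::export]]
List cpp_monotone_align(NumericMatrix S, double s_min, bool forbid_self) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix M(n + 1, m + 1); // zero-initialised prefix-best table

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = M(i - 1, j) > M(i, j - 1) ? M(i - 1, j) : M(i, j - 1);
      const double s = S(i - 1, j - 1);
      if (s >= s_min && !(forbid_self && i == j)) {
        const double cand = M(i - 1, j - 1) + s;
        if (cand > best) best = cand;
      }
      M(i, j) = best;
    }
  }

  std::vector<int> ri, rj;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    const double s = S(i - 1, j - 1);
    const bool elig = s >= s_min && !(forbid_self && i == j);
    if (elig && M(i, j) == M(i - 1, j - 1) + s) {
      ri.push_back(i);
      rj.push_back(j);
      --i; --j;
    } else if (M(i, j) == M(i - 1, j)) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(ri.begin(), ri.end());
  std::reverse(rj.begin(), rj.end());

  const int k = (int)ri.size();
  IntegerMatrix pairs(k, 2);
  for (int q = 0; q < k; ++q) {
    pairs(q, 0) = ri[q];
    pairs(q, 1) = rj[q];
  }
  return List::create(_["pairs"] = pairs, _["score"] = M(n, m));
}
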