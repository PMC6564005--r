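#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive per-unit selection of round 1 vs round 2 for each rater,
// minimizing the sum of pairwise distances between the chosen sequences.
//
// d:  symmetric distance matrix over the unique sequences of the unit
// i1: 0-based index into d of each rater's round-1 sequence
// i2: 0-based index of each rater's round-2 sequence
//
// Raters with i1 == i2 are fixed (their choice is immaterial and reported as
// round 1). The remaining "free" raters are enumerated over all 2^f masks in
// ascending order with the first free rater as the most significant bit, so
// the first strict minimum encountered is the lexicographically smallest
// selection preferring round 1 — the documented tie-break.
// [[Rcpp::export]]
List select_optimal_cpp(NumericMatrix d, IntegerVector i1, IntegerVector i2) {
  const int m = i1.size();
  if (i2.size() != m) stop("i1 and i2 must have equal length");
  std::vector<int> freeIdx;
  for (int i = 0; i < m; ++i) {
    if (i1[i] < 0 || i1[i] >= d.nrow() || i2[i] < 0 || i2[i] >= d.nrow())
      stop("sequence index out of range of the distance matrix");
    if (i1[i] != i2[i]) freeIdx.push_back(i);
  }
  const int f = (int) freeIdx.size();
  if (f > 30) stop("more than 30 raters with distinct rounds: exhaustive search infeasible");

  std::vector<int> cur(m);
  for (int i = 0; i < m; ++i) cur[i] = i1[i];

  double best = R_PosInf;
  unsigned long long bestMask = 0;
  const unsigned long long nMask = 1ULL << f;

  for (unsigned long long mask = 0; mask < nMask; ++mask) {
    for (int k = 0; k < f; ++k) {
      const bool useR2 = (mask >> (f - 1 - k)) & 1ULL;
      const int i = freeIdx[k];
      cur[i] = useR2 ? i2[i] : i1[i];
    }
    double tot = 0.0;
    for (int i = 0; i < m - 1; ++i)
      for (int j = i + 1; j < m; ++j)
        tot += d(cur[i], cur[j]);
    if (tot < best - 1e-12) {
      best = tot;
      bestMask = mask;
      if (best <= 1e-15) break;  // zero is the global minimum; earliest mask wins ties
    }
    if ((mask & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector choice(m, 1);
  for (int k = 0; k < f; ++k) {
    if ((bestMask >> (f - 1 - k)) & 1ULL) choice[freeIdx[k]] = 2;
  }
  if (m < 2) best = 0.0;
  return List::create(_["choice"] = choice,
                      _["total"] = best,
                      _["n_free"] = f);
}
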