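#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy 1:k nearest-neighbour matching without replacement.
//
// Controls are sorted by (score, tiebreak rank). Availability is tracked
// with two union-find "next live position" / "previous live position"
// structures (path-halving), plus the static start index of each equal-score
// run. For a case score sc, lower_bound splits the pool: positions to the
// left have score < sc, the right side starts at score >= sc.
//
//  * right candidate: first available position at/after the split — within
//    its run this is automatically the smallest tiebreak rank;
//  * left candidate: the run holding the nearest available position to the
//    left is located, then its first available member (smallest rank in the
//    run) is used, because all members of a run are equidistant from sc.
//
// Ties across the two sides resolve by smaller tiebreak rank.
//
// Returns an n_case x ratio matrix of 1-based control indices.
// [[Rcpp::export]]
IntegerMatrix greedy_match_cpp(NumericVector case_scores,
                               NumericVector ctrl_scores,
                               IntegerVector ctrl_rank,
                               int ratio) {
  const int nca = case_scores.size();
  const int nco = ctrl_scores.size();
  if (nco < nca * ratio)
    stop("control pool exhausted: need %d controls, have %d",
         nca * ratio, nco);

  std::vector<int> ord(nco);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (ctrl_scores[a] != ctrl_scores[b])
      return ctrl_scores[a] < ctrl_scores[b];
    return ctrl_rank[a] < ctrl_rank[b];
  });
  std::vector<double> s(nco);
  for (int i = 0; i < nco; ++i) s[i] = ctrl_scores[ord[i]];

  // static first index of each equal-score run
  std::vector<int> run_start(nco);
  for (int i = 0; i < nco; ++i)
    run_start[i] = (i > 0 && s[i] == s[i - 1]) ? run_start[i - 1] : i;

  // fnext[i]: smallest live j >= i (fnext[nco] = nco sentinel: none)
  // fprev[i+1]: largest live j <= i, stored shifted by +1 (fprev[0] = none)
  std::vector<int> fnext(nco + 1), fprev(nco + 2);
  for (int i = 0; i <= nco; ++i) fnext[i] = i;
  for (int i = 0; i <= nco + 1; ++i) fprev[i] = i;

  auto find_next = [&](int i) {
    while (fnext[i] != i) { fnext[i] = fnext[fnext[i]]; i = fnext[i]; }
    return i;
  };
  auto find_prev = [&](int i) {
    while (fprev[i] != i) { fprev[i] = fprev[fprev[i]]; i = fprev[i]; }
    return i;
  };
  auto remove_pos = [&](int p) { // 0-based sorted position
    fnext[p] = p + 1;
    fprev[p + 1] = p;
  };

  IntegerMatrix out(nca, ratio);
  for (int ci = 0; ci < nca; ++ci) {
    const double sc = case_scores[ci];
    const int split =
        static_cast<int>(std::lower_bound(s.begin(), s.end(), sc) - s.begin());
    for (int r = 0; r < ratio; ++r) {
      const int rpos = find_next(split);           // nco if exhausted
      int lcand = -1;
      const int lnear = find_prev(split) - 1;      // -1 if exhausted
      if (lnear >= 0)
        lcand = find_next(run_start[lnear]);       // min rank in that run
      const bool has_r = rpos < nco;
      const bool has_l = lcand >= 0;
      if (!has_r && !has_l)
        stop("control pool exhausted at case %d", ci + 1);
      int pick;
      if (!has_r) pick = lcand;
      else if (!has_l) pick = rpos;
      else {
        const double dr = std::fabs(s[rpos] - sc);
        const double dl = std::fabs(s[lcand] - sc);
        if (dr < dl) pick = rpos;
        else if (dl < dr) pick = lcand;
        else pick = (ctrl_rank[ord[lcand]] < ctrl_rank[ord[rpos]])
                      ? lcand : rpos;
      }
      out(ci, r) = ord[pick] + 1;
      remove_pos(pick);
    }
  }
  return out;
}
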