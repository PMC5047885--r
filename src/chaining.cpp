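#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Sparse DP over anchor dots. A dot j can precede dot i in a chain iff
// oa[j] < oa[i] with at most max_gap intervening gene ranks on genome A,
// and the analogous condition on genome B in the direction fixed by the
// chain orientation (ob increasing for "same", decreasing for "inverted").
// Gaps are counted as intervening ranks: gap = |delta| - 1 <= max_gap.
// Input must be sorted by (oa, ob); scores/prev are per input dot, prev is
// 1-based with 0 meaning chain start.

// [[Rcpp::export]]
List chain_dp_cpp(IntegerVector oa, IntegerVector ob, int max_gap,
                  bool inverted) {
  const int n = oa.size();
  IntegerVector score(n, 1), prev(n, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      if (oa[j] >= oa[i]) continue;
      if (oa[i] - oa[j] - 1 > max_gap) continue;
      int db = inverted ? (ob[j] - ob[i]) : (ob[i] - ob[j]);
      if (db <= 0 || db - 1 > max_gap) continue;
      if (score[j] + 1 > score[i]) {
        score[i] = score[j] + 1;
        prev[i] = j + 1;
      }
    }
  }
  return List::create(_["score"] = score, _["prev"] = prev);
}

static int best_chain_len(const std::vector<int>& oa,
                          const std::vector<int>& ob,
                          int max_gap, bool inverted) {
  const int n = (int)oa.size();
  std::vector<int> score(n, 1);
  int best = n > 0 ? 1 : 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      if (oa[j] >= oa[i]) continue;
      if (oa[i] - oa[j] - 1 > max_gap) continue;
      int db = inverted ? (ob[j] - ob[i]) : (ob[i] - ob[j]);
      if (db <= 0 || db - 1 > max_gap) continue;
      if (score[j] + 1 > score[i]) score[i] = score[j] + 1;
    }
    if (score[i] > best) best = score[i];
  }
  return best;
}

// Longest max-gap-bounded monotone chain over both orientations.
// [[Rcpp::export]]
int longest_chain_cpp(IntegerVector oa, IntegerVector ob, int max_gap) {
  const int n = oa.size();
  if (n == 0) return 0;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (oa[a] != oa[b]) return oa[a] < oa[b];
    return ob[a] < ob[b];
  });
  std::vector<int> sa(n), sb(n);
  for (int i = 0; i < n; ++i) { sa[i] = oa[idx[i]]; sb[i] = ob[idx[i]]; }
  int same = best_chain_len(sa, sb, max_gap, false);
  int inv  = best_chain_len(sa, sb, max_gap, true);
  return same > inv ? same : inv;
}

// Permutation null for block significance: place n_anchors uniformly on a
// len_a x len_b gene-rank grid and record the longest chain, n_perm times.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector chain_null_cpp(int n_anchors, int len_a, int len_b,
                             int n_perm, int max_gap) {
  IntegerVector out(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    IntegerVector pa = (n_anchors <= len_a)
      ? Rcpp::sample(len_a, n_anchors, false)
      : Rcpp::sample(len_a, n_anchors, true);
    IntegerVector pb = (n_anchors <= len_b)
      ? Rcpp::sample(len_b, n_anchors, false)
      : Rcpp::sample(len_b, n_anchors, true);
    out[p] = longest_chain_cpp(pa, pb, max_gap);
  }
  return out;
}
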