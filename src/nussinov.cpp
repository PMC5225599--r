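#include <Rcpp.h>
#include <string>
#include <vector>
#include <stack>
#include <utility>

// Maximum base-pairing fold (Nussinov-style) with a cap on pair span and a
// minimum hairpin loop, returning one optimal structure in dot-bracket
// notation.
//
// Scoring is lexicographic: the number of pairs is maximized first, and
// among count-maximal structures the number of G:C pairs is maximized.
// Each pair scores K + [G:C] with K > n/2 >= any attainable G:C count, so
// the total pair count of the returned structure always equals the
// unweighted Nussinov maximum; the secondary term only resolves the
// massive tie degeneracy in favour of G:C stems.
//
// Banded DP: pairs farther apart than max_dist are forbidden, so enclosed
// intervals never exceed the band and a linear chain DP combines them
// across the whole sequence. Traceback prefers closing the outermost pair
// (i, j) whenever that is optimal.

typedef long long score_t;

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

static inline bool is_gc(char a, char b) {
  return (a == 'G' && b == 'C') || (a == 'C' && b == 'G');
}

// [[Rcpp::export]]
std::string nussinov_fold_cpp(std::string seq, int max_dist, int min_loop) {
  const int n = (int) seq.size();
  if (n == 0) return std::string();
  const int W = max_dist;
  const score_t K = (score_t) n / 2 + 2;
  // M[i*(W+1)+d] = best score within [i, i+d], d <= W
  std::vector<score_t> M((size_t) n * (W + 1), 0);
  auto Mi = [&](int i, int j) -> score_t {
    if (j <= i) return 0;
    return M[(size_t) i * (W + 1) + (j - i)];
  };
  auto pscore = [&](int i, int j) -> score_t {
    return K + (is_gc(seq[i], seq[j]) ? 1 : 0);
  };
  for (int d = min_loop + 1; d <= W; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      score_t best = Mi(i + 1, j);
      score_t v = Mi(i, j - 1);
      if (v > best) best = v;
      if (can_pair(seq[i], seq[j])) {
        v = Mi(i + 1, j - 1) + pscore(i, j);
        if (v > best) best = v;
      }
      for (int k = i; k < j; ++k) {
        v = Mi(i, k) + Mi(k + 1, j);
        if (v > best) best = v;
      }
      M[(size_t) i * (W + 1) + d] = best;
    }
  }
  // chain DP across the whole sequence: G[j+1] = best score over [0, j]
  std::vector<score_t> G(n + 1, 0);
  std::vector<int> choice(n, -1);          // paired partner i of j, or -1
  for (int j = 0; j < n; ++j) {
    score_t pbest = -1;
    int parg = -1;
    int lo = j - W; if (lo < 0) lo = 0;
    for (int i = lo; i <= j - min_loop - 1; ++i) {
      if (!can_pair(seq[i], seq[j])) continue;
      score_t v = G[i] + pscore(i, j) + Mi(i + 1, j - 1);
      if (v > pbest) { pbest = v; parg = i; }   // smallest i wins ties
    }
    // prefer pairing j on ties: keeps planted stems closed outermost-first
    if (pbest >= G[j]) { G[j + 1] = pbest; choice[j] = parg; }
    else { G[j + 1] = G[j]; choice[j] = -1; }
  }
  std::string db(n, '.');
  // traceback of a banded interval [a, b]
  std::stack<std::pair<int, int> > st;
  auto trace_interval = [&](int a, int b) {
    st.push(std::make_pair(a, b));
    while (!st.empty()) {
      int i = st.top().first, j = st.top().second;
      st.pop();
      if (j - i <= min_loop) continue;
      score_t m = Mi(i, j);
      if (m == 0) continue;
      if (can_pair(seq[i], seq[j]) && m == Mi(i + 1, j - 1) + pscore(i, j)) {
        db[i] = '('; db[j] = ')';
        st.push(std::make_pair(i + 1, j - 1));
        continue;
      }
      if (m == Mi(i + 1, j)) { st.push(std::make_pair(i + 1, j)); continue; }
      if (m == Mi(i, j - 1)) { st.push(std::make_pair(i, j - 1)); continue; }
      bool done = false;
      for (int k = i; k < j && !done; ++k) {
        if (m == Mi(i, k) + Mi(k + 1, j)) {
          st.push(std::make_pair(i, k));
          st.push(std::make_pair(k + 1, j));
          done = true;
        }
      }
    }
  };
  // following choice[j] always stays on an optimal path
  int j = n - 1;
  while (j >= 0) {
    int i = choice[j];
    if (i < 0) { --j; continue; }
    db[i] = '('; db[j] = ')';
    if (j - 1 >= i + 1) trace_interval(i + 1, j - 1);
    j = i - 1;
  }
  return db;
}
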