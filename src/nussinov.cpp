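#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Maximum base-pairing (Nussinov) fold used by the synthetic-assay
// generator. No energy model: score = number of pairs, minimum hairpin
// loop enforced, ties broken deterministically in favour of pairing the
// 5'-most partner. Alphabet A,C,G,U; allowed pairs: AU, UA, GC, CG, GU, UG.

static inline int base_code(char ch) {
  switch (ch) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default:  return -1;
  }
}

static inline bool can_pair(int a, int b) {
  if (a > b) std::swap(a, b);
  return (a == 0 && b == 3) || (a == 1 && b == 2) || (a == 2 && b == 3);
}

static inline int pair_score(const std::vector<std::vector<int> > &M,
                             const std::vector<int> &s,
                             int i, int k, int j) {
  // score of region [i, j] when i pairs with k
  int sc = 1;
  if (k - 1 >= i + 1) sc += M[i + 1][k - 1];
  if (k + 1 <= j)     sc += M[k + 1][j];
  return sc;
}

// [[Rcpp::export]]
std::string cpp_fold_nussinov(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = base_code(seq[i]);
    if (s[i] < 0) stop("invalid letter '%s' in RNA sequence (expected A/C/G/U)",
                       std::string(1, seq[i]).c_str());
  }
  if (n == 0) return "";

  // M[i][j]: max number of pairs in s[i..j]; spans shorter than
  // min_loop + 2 stay 0 (no legal pair fits)
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(s[i], s[k])) continue;
        int cand = pair_score(M, s, i, k, j);
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }

  std::string db(n, '.');
  std::stack<std::pair<int, int> > todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (j - i < min_loop + 1 || M[i][j] == 0) continue;
    int target = M[i][j];
    // prefer pairing i with the 5'-most k achieving the optimum;
    // fall back to leaving i unpaired
    int chosen = -1;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(s[i], s[k])) continue;
      if (pair_score(M, s, i, k, j) == target) { chosen = k; break; }
    }
    if (chosen >= 0) {
      db[i] = '(';
      db[chosen] = ')';
      if (chosen - 1 >= i + 1) todo.push(std::make_pair(i + 1, chosen - 1));
      if (chosen + 1 <= j - 1) todo.push(std::make_pair(chosen + 1, j));
    } else {
      todo.push(std::make_pair(i + 1, j));
    }
  }
  return db;
}
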