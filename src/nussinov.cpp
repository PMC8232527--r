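#include <Rcpp.h>
#include <string>
#include <vector>
#include <stack>
using namespace Rcpp;

// Watson-Crick + wobble pairing over A,C,G,U
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing structure with a minimum hairpin loop of 3
// unpaired bases (pair (i,j) admissible iff j - i >= 4), rendered as
// dot-bracket. Deterministic traceback: at each subproblem, pairing the
// left end with the smallest admissible partner achieving the optimum
// is preferred over leaving it unpaired.
// [[Rcpp::export(name = ".nussinov_fold")]]
std::string nussinov_fold(std::string seq) {
  const int n = seq.size();
  std::string db(n, '.');
  if (n < 5) return db;
  std::vector<std::vector<int>> N(n, std::vector<int>(n, 0));
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[i + 1][j];  // i unpaired
      for (int k = i + 4; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int v = 1 + (k - i > 4 ? N[i + 1][k - 1] : 0) +
                (k < j ? N[k + 1][j] : 0);
        if (v > best) best = v;
      }
      N[i][j] = best;
    }
  }
  std::stack<std::pair<int, int>> todo;
  todo.push({0, n - 1});
  while (!todo.empty()) {
    auto [i, j] = todo.top();
    todo.pop();
    if (j - i < 4) continue;
    bool paired = false;
    for (int k = i + 4; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int v = 1 + (k - i > 4 ? N[i + 1][k - 1] : 0) +
              (k < j ? N[k + 1][j] : 0);
      if (v == N[i][j]) {  // leftmost admissible partner
        db[i] = '(';
        db[k] = ')';
        if (k - i > 4) todo.push({i + 1, k - 1});
        if (k < j) todo.push({k + 1, j});
        paired = true;
        break;
      }
    }
    if (!paired) todo.push({i + 1, j});
  }
  return db;
}
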