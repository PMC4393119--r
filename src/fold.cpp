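#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// weighted Nussinov folding with a minimum loop constraint.
// pair weights: GC=3, AU=2, GU=1 (0 = cannot pair).

static inline int pair_w(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, int min_loop) {
  int n = seq.size();
  std::vector<int> dp;
  dp.assign((size_t)n * n, 0);
  auto D = [&](int i, int j) -> int& { return dp[(size_t)i * n + j]; };

  // dp over interval length; D(i,j) = best score on seq[i..j]
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = D(i + 1, j);  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_w(seq[i], seq[k]);
        if (!w) continue;
        int inner = (k - i - 1 > min_loop) ? D(i + 1, k - 1) : 0;
        int rest = (k + 1 <= j) ? D(k + 1, j) : 0;
        int s = w + inner + rest;
        if (s > best) best = s;
      }
      D(i, j) = best;
    }
  }

  // deterministic traceback: prefer pairing, smallest partner k, on ties
  IntegerVector partner(n, -1);
  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    int target = D(i, j);
    bool done = false;
    for (int k = i + min_loop + 1; k <= j && !done; ++k) {
      int w = pair_w(seq[i], seq[k]);
      if (!w) continue;
      int inner = (k - i - 1 > min_loop) ? D(i + 1, k - 1) : 0;
      int rest = (k + 1 <= j) ? D(k + 1, j) : 0;
      if (w + inner + rest == target) {
        partner[i] = k;
        partner[k] = i;
        db[i] = '(';
        db[k] = ')';
        if (k - i - 1 > min_loop) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
        done = true;
      }
    }
    if (!done) stack.push_back(std::make_pair(i + 1, j));
  }

  int score = (n > 1) ? D(0, n - 1) : 0;
  return List::create(_["dotbracket"] = db, _["score"] = score,
                      _["partner"] = partner);
}
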