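#include <Rcpp.h>
using namespace Rcpp;

// Nussinov-style maximum-weight, pseudoknot-free secondary structure with a
// minimum hairpin loop of `min_loop` unpaired bases. Pair weights GC=3,
// AU=2, GU=1; T and U equivalent; anything else (N, ...) unpairable.
// Returns the dot-bracket structure and the total pairing score
// (mfe proxy = -score).

static inline int encode_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return 4;
  }
}

// weight lookup: index = 5*a + b
static const int PAIR_W[25] = {
  // A      C  G  T  N
  0, 0, 0, 2, 0,   // A
  0, 0, 3, 0, 0,   // C
  0, 3, 0, 1, 0,   // G
  2, 0, 1, 0, 0,   // T
  0, 0, 0, 0, 0    // N
};

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, int min_loop = 3) {
  int n = (int)seq.size();
  if (n == 0)
    return List::create(_["structure"] = "", _["score"] = 0.0);

  std::vector<int> e(n);
  for (int i = 0; i < n; ++i) e[i] = encode_base(seq[i]);

  // W stored as flat row-major n x n
  std::vector<int> W((size_t)n * n, 0);
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = W[(size_t)(i + 1) * n + j];  // i unpaired
      const int ei5 = 5 * e[i];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = PAIR_W[ei5 + e[k]];
        if (w > 0) {
          int v = w + (k > i + 1 ? W[(size_t)(i + 1) * n + (k - 1)] : 0)
                    + (k < j ? W[(size_t)(k + 1) * n + j] : 0);
          if (v > best) best = v;
        }
      }
      W[(size_t)i * n + j] = best;
    }
  }

  std::string db(n, '.');
  std::vector<std::pair<int, int> > todo;
  todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (i >= j || j - i < min_loop + 1 || W[(size_t)i * n + j] == 0) continue;
    if (W[(size_t)i * n + j] == W[(size_t)(i + 1) * n + j]) {
      todo.push_back(std::make_pair(i + 1, j));  // prefer i unpaired on ties
      continue;
    }
    const int ei5 = 5 * e[i];
    for (int k = i + min_loop + 1; k <= j; ++k) {
      int w = PAIR_W[ei5 + e[k]];
      if (w > 0) {
        int v = w + (k > i + 1 ? W[(size_t)(i + 1) * n + (k - 1)] : 0)
                  + (k < j ? W[(size_t)(k + 1) * n + j] : 0);
        if (v == W[(size_t)i * n + j]) {
          db[i] = '(';
          db[k] = ')';
          if (k > i + 1) todo.push_back(std::make_pair(i + 1, k - 1));
          if (k < j) todo.push_back(std::make_pair(k + 1, j));
          break;
        }
      }
    }
  }
  return List::create(_["structure"] = db,
                      _["score"] = (double)W[(size_t)0 * n + (n - 1)]);
}
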