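#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Watson-Crick + GU wobble pairing.
static inline bool pairs(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing (Nussinov) folder with a minimum hairpin loop of
// `min_loop` unpaired nucleotides. Deterministic traceback preference:
// close the pair (i,j) when optimal, else leave i unpaired, else leave j
// unpaired, else bifurcate at the smallest split point.
static std::string nussinov_one(const std::string& s, int min_loop) {
  const int n = (int) s.size();
  std::string db(n, '.');
  if (n < min_loop + 2) return db;
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];
      if (M[i][j - 1] > best) best = M[i][j - 1];
      if (pairs(s[i], s[j]) && j - i > min_loop) {
        int v = (i + 1 <= j - 1 ? M[i + 1][j - 1] : 0) + 1;
        if (v > best) best = v;
      }
      for (int k = i + 1; k < j; ++k) {
        int v = M[i][k] + M[k + 1][j];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  // iterative traceback
  std::vector<std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    int m = M[i][j];
    if (m == 0) continue;
    if (pairs(s[i], s[j]) && j - i > min_loop &&
        m == (i + 1 <= j - 1 ? M[i + 1][j - 1] : 0) + 1) {
      db[i] = '(';
      db[j] = ')';
      stack.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    if (m == M[i + 1][j]) { stack.push_back(std::make_pair(i + 1, j)); continue; }
    if (m == M[i][j - 1]) { stack.push_back(std::make_pair(i, j - 1)); continue; }
    bool split = false;
    for (int k = i + 1; k < j && !split; ++k) {
      if (m == M[i][k] + M[k + 1][j]) {
        stack.push_back(std::make_pair(i, k));
        stack.push_back(std::make_pair(k + 1, j));
        split = true;
      }
    }
    if (!split) Rcpp::stop("nussinov traceback failed");
  }
  return db;
}

// [[Rcpp::export]]
CharacterVector nussinov_fold_cpp(CharacterVector seqs, int min_loop) {
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = nussinov_one(s, min_loop);
  }
  return out;
}

// Longest contiguous complementary run between a and the reverse of b under
// the antiparallel zipper alignment: position t of a is apposed to position
// t of rev(b), and the run is the longest stretch of consecutive apposed
// positions that can all pair (Watson-Crick or GU).
// [[Rcpp::export]]
IntegerVector max_complementary_run_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  if (b.size() != n) Rcpp::stop("length mismatch");
  IntegerVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string x = as<std::string>(a[r]);
    std::string y = as<std::string>(b[r]);
    std::reverse(y.begin(), y.end());
    const int m = (int) std::min(x.size(), y.size());
    int best = 0, cur = 0;
    for (int t = 0; t < m; ++t) {
      if (pairs(x[t], y[t])) {
        ++cur;
        if (cur > best) best = cur;
      } else {
        cur = 0;
      }
    }
    out[r] = best;
  }
  return out;
}
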