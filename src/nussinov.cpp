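#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair maximization (Nussinov) over canonical pairs A:U(T), G:C, G:U(T)
// with a minimum hairpin loop of `min_loop` unpaired bases. DNA input is
// treated as the transcribed RNA (T read as U).

static inline bool can_pair(char a, char b) {
  if (a == 'U') a = 'T';
  if (b == 'U') b = 'T';
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

static void traceback(const std::vector<std::vector<int> > &M,
                      const std::string &s, int min_loop,
                      int i, int j, std::vector<std::pair<int,int> > &pairs) {
  while (i < j) {
    if (M[i][j] == 0) return;
    // prefer closing the pair when co-optimal: keeps stems contiguous
    if (j - i - 1 >= min_loop && can_pair(s[i], s[j]) &&
        M[i][j] == M[i + 1][j - 1] + 1) {
      pairs.push_back(std::make_pair(i, j));
      ++i; --j; continue;
    }
    if (M[i][j] == M[i + 1][j]) { ++i; continue; }
    if (M[i][j] == M[i][j - 1]) { --j; continue; }
    bool split = false;
    for (int k = i + 1; k < j; ++k) {
      if (M[i][j] == M[i][k] + M[k + 1][j]) {
        traceback(M, s, min_loop, i, k, pairs);
        i = k + 1;
        split = true;
        break;
      }
    }
    if (!split) return; // unreachable for a consistent table
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  int n = seq.size();
  if (n == 0) {
    return List::create(_["max_pairs"] = 0,
                        _["pairs"] = IntegerMatrix(0, 2));
  }
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 1; len < n; ++len) {
    for (int i = 0; i + len < n; ++i) {
      int j = i + len;
      int best = std::max(M[i + 1][j], M[i][j - 1]);
      if (can_pair(seq[i], seq[j]) && j - i - 1 >= min_loop) {
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
  std::vector<std::pair<int,int> > pairs;
  traceback(M, seq, min_loop, 0, n - 1, pairs);
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first + 1;   // 1-based for R
    pm(r, 1) = pairs[r].second + 1;
  }
  return List::create(_["max_pairs"] = M[0][n - 1], _["pairs"] = pm);
}
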