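#include <Rcpp.h>
#include <string>
#include <vector>

// Exact longest common substring (longest block of uninterrupted identity)
// between two nucleotide strings.  Classic O(n*m) dynamic programme with a
// rolling row; 'N' (or any non-ACGT byte) never matches anything, including
// another 'N'.

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
int lcs_length_cpp(std::string a, std::string b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (size_t i = 1; i <= n; ++i) {
    const char ca = a[i - 1];
    const bool ok_a = is_acgt(ca);
    for (size_t j = 1; j <= m; ++j) {
      if (ok_a && ca == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) best = cur[j];
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return best;
}
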