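#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Optimal string alignment (restricted Damerau-Levenshtein): unit-cost
// insertions, deletions, substitutions and adjacent transpositions, with
// the restriction that no substring is edited twice. This is the standard
// distance used for scientific-name fuzzy matching.
static int osa_dist(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> d0(m + 1), d1(m + 1), d2(m + 1);
  for (int j = 0; j <= m; ++j) d1[j] = j;
  for (int i = 1; i <= n; ++i) {
    d2[0] = i;
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int best = std::min(std::min(d2[j - 1] + 1, d1[j] + 1), d1[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        best = std::min(best, d0[j - 2] + 1);
      d2[j] = best;
    }
    std::swap(d0, d1);
    std::swap(d1, d2);
  }
  return d1[m];
}

// [[Rcpp::export(name = ".osa_pair")]]
IntegerVector osa_pair(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String sa = a[a.size() == 1 ? 0 : i];
    String sb = b[b.size() == 1 ? 0 : i];
    if (sa == NA_STRING || sb == NA_STRING) {
      out[i] = NA_INTEGER;
    } else {
      out[i] = osa_dist(std::string(sa.get_cstring()),
                        std::string(sb.get_cstring()));
    }
  }
  return out;
}

// [[Rcpp::export(name = ".osa_to_many")]]
IntegerVector osa_to_many(std::string query, CharacterVector candidates) {
  R_xlen_t n = candidates.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String s = candidates[i];
    if (s == NA_STRING) out[i] = NA_INTEGER;
    else out[i] = osa_dist(query, std::string(s.get_cstring()));
  }
  return out;
}
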