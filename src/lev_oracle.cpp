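// Naive memoized-recursion Levenshtein distance. Deliberately written as a
// direct transcription of the recurrence (not the iterative DP used by
// utils::adist) so it can serve as an independent cross-check.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

int lev_rec(const std::string& a, const std::string& b, int i, int j,
            std::vector<int>& memo, int nb) {
  if (i == 0) return j;
  if (j == 0) return i;
  int& m = memo[i * (nb + 1) + j];
  if (m >= 0) return m;
  int sub = lev_rec(a, b, i - 1, j - 1, memo, nb) +
            (a[i - 1] == b[j - 1] ? 0 : 1);
  int del = lev_rec(a, b, i - 1, j, memo, nb) + 1;
  int ins = lev_rec(a, b, i, j - 1, memo, nb) + 1;
  m = std::min(sub, std::min(del, ins));
  return m;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".lev_oracle_cpp")]]
IntegerMatrix lev_oracle_cpp(CharacterVector a, CharacterVector b) {
  const int na = a.size(), nb = b.size();
  IntegerMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    std::string sa = as<std::string>(a[i]);
    for (int j = 0; j < nb; ++j) {
      std::string sb = as<std::string>(b[j]);
      std::vector<int> memo((sa.size() + 1) * (sb.size() + 1), -1);
      out(i, j) = lev_rec(sa, sb, sa.size(), sb.size(), memo, sb.size());
    }
  }
  return out;
}
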