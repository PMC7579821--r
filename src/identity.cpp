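#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Semi-global alignment DP: the pattern is aligned globally, the subject
// locally (its unaligned prefix and suffix are free). Unit scoring: match
// +1, mismatch -1, gap -1 per position, linear gaps. Among alignments of
// optimal score the one with the most matches is reported, so the match
// count (and hence identity) is deterministic.
//
// [[Rcpp::export(name = ".semiglobal_matches")]]
List semiglobal_matches(std::string pattern, std::string subject) {
  const int m = (int) pattern.size();
  const int n = (int) subject.size();
  std::vector<int> prev_s(n + 1, 0), prev_m(n + 1, 0);
  std::vector<int> cur_s(n + 1), cur_m(n + 1);
  for (int i = 1; i <= m; ++i) {
    cur_s[0] = -i;
    cur_m[0] = 0;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      const bool is_match = (pc == subject[j - 1]);
      int bs = prev_s[j - 1] + (is_match ? 1 : -1);
      int bm = prev_m[j - 1] + (is_match ? 1 : 0);
      const int us = prev_s[j] - 1;   // gap in subject (pattern char vs -)
      if (us > bs || (us == bs && prev_m[j] > bm)) { bs = us; bm = prev_m[j]; }
      const int ls = cur_s[j - 1] - 1; // gap in pattern (- vs subject char)
      if (ls > bs || (ls == bs && cur_m[j - 1] > bm)) { bs = ls; bm = cur_m[j - 1]; }
      cur_s[j] = bs;
      cur_m[j] = bm;
    }
    std::swap(prev_s, cur_s);
    std::swap(prev_m, cur_m);
  }
  int bs = prev_s[0], bm = prev_m[0];
  for (int j = 1; j <= n; ++j) {
    if (prev_s[j] > bs || (prev_s[j] == bs && prev_m[j] > bm)) {
      bs = prev_s[j];
      bm = prev_m[j];
    }
  }
  return List::create(_["score"] = bs, _["matches"] = bm);
}
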