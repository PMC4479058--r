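#include <Rcpp.h>
using namespace Rcpp;

// Ungapped end-anchored scan: for each read, the minimum-Hamming-distance
// placement fully inside any reference. A read that fits nowhere, or whose
// minimum exceeds the budget, gets NA. Ties are ties *across references* at
// the minimal distance (equal-distance placements within one reference are
// not ambiguous). 'N' never matches, so it always costs a mismatch.
// [[Rcpp::export]]
List hamming_scan_cpp(CharacterVector reads, CharacterVector refs,
                      int max_mismatches) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::string> R(nf);
  for (int j = 0; j < nf; ++j) R[j] = as<std::string>(refs[j]);

  IntegerVector best_ref(nr, NA_INTEGER);
  IntegerVector best_mm(nr, NA_INTEGER);
  IntegerVector best_off(nr, NA_INTEGER);
  LogicalVector tie(nr, false);

  for (int i = 0; i < nr; ++i) {
    const std::string q = as<std::string>(reads[i]);
    const int lq = (int) q.size();
    int best = max_mismatches + 1, bref = -1, boff = -1;
    bool t = false;
    for (int j = 0; j < nf; ++j) {
      const std::string &s = R[j];
      const int ls = (int) s.size();
      for (int off = 0; off + lq <= ls; ++off) {
        int mm = 0;
        for (int k = 0; k < lq; ++k) {
          if (q[k] != s[off + k] && ++mm > best) break;
        }
        if (mm > best) continue;
        if (mm < best) {
          best = mm; bref = j; boff = off; t = false;
        } else if (best <= max_mismatches && j != bref) {
          t = true;  // equal minimal distance on a different reference
        }
      }
    }
    if (best <= max_mismatches && bref >= 0) {
      best_ref[i] = bref + 1;
      best_mm[i] = best;
      best_off[i] = boff + 1;
      tie[i] = t;
    }
  }
  return List::create(_["ref"] = best_ref, _["mismatches"] = best_mm,
                      _["offset"] = best_off, _["tie"] = tie);
}
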