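#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// true when the u-long motif starting at `a` repeats with a shorter period
// that divides u (e.g. ATAT is 2 x AT), so the run is reported at the
// smaller period instead
static bool motif_reducible(const char *s, int a, int u) {
  for (int d = 1; d < u; ++d) {
    if (u % d != 0) continue;
    bool periodic = true;
    for (int i = d; i < u; ++i) {
      if (s[a + i] != s[a + i - d]) { periodic = false; break; }
    }
    if (periodic) return true;
  }
  return false;
}

// Maximal perfect tandem repeats with unit lengths 1..max_unit.
// A run at period u is the maximal stretch with s[i] == s[i+u]; only whole
// units are reported (MISA convention). Non-ACGT characters terminate runs.
// min_units[u-1] is the minimum unit count for unit length u.
// [[Rcpp::export]]
DataFrame ssr_scan_cpp(std::string seq, IntegerVector min_units, int max_unit) {
  if ((int)min_units.size() < max_unit) stop("min_units too short");
  const char *s = seq.c_str();
  const int n = (int)seq.size();
  std::vector<int> starts, ends, units, nrep;

  for (int u = 1; u <= max_unit; ++u) {
    int i = 0;
    while (i + u < n) {
      if (!is_acgt(s[i]) || !is_acgt(s[i + u]) || s[i] != s[i + u]) {
        ++i;
        continue;
      }
      int j = i;
      while (j + u < n && is_acgt(s[j + u]) && s[j] == s[j + u]) ++j;
      // period holds on [i, j); repeat region is [i, j + u)
      int len = j + u - i;
      int k = len / u;
      if (k >= min_units[u - 1] && !motif_reducible(s, i, u)) {
        starts.push_back(i);
        ends.push_back(i + k * u);
        units.push_back(u);
        nrep.push_back(k);
        i = i + k * u;  // leftmost non-overlapping: resume at the locus end
      } else {
        // a shorter run cannot reach the threshold from inside this region,
        // but a fresh run may start within the trailing partial unit
        i = j + 1;
      }
    }
  }
  return DataFrame::create(
    _["start"] = IntegerVector(starts.begin(), starts.end()),
    _["end"] = IntegerVector(ends.begin(), ends.end()),
    _["unit_len"] = IntegerVector(units.begin(), units.end()),
    _["n_units"] = IntegerVector(nrep.begin(), nrep.end()));
}
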