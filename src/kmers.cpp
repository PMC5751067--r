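#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N or any non-ACGT letter breaks the window
  }
}

// k-mer multiplicity histogram over a set of sequences.
// Windows containing non-ACGT characters are skipped; k is capped at 31 so a
// k-mer packs into one 64-bit word (2 bits per base).
// [[Rcpp::export]]
DataFrame kmer_histogram_cpp(CharacterVector seqs, int k, bool canonical) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    SEXP el = STRING_ELT(seqs, s);
    const char *str = CHAR(el);
    const int n = LENGTH(el);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bits(str[i]);
      if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      if (++valid >= k) {
        uint64_t key = canonical ? std::min(fwd, rev) : fwd;
        ++counts[key];
      }
    }
  }

  // histogram: multiplicity -> number of distinct k-mers
  std::unordered_map<uint32_t, double> hist;
  for (const auto &kv : counts) hist[kv.second] += 1.0;

  std::vector<uint32_t> mult;
  mult.reserve(hist.size());
  for (const auto &kv : hist) mult.push_back(kv.first);
  std::sort(mult.begin(), mult.end());

  IntegerVector m(mult.size());
  NumericVector d(mult.size());
  for (size_t i = 0; i < mult.size(); ++i) {
    m[i] = (int)mult[i];
    d[i] = hist[mult[i]];
  }
  return DataFrame::create(_["multiplicity"] = m, _["distinct"] = d);
}
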