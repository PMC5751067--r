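#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

namespace {

struct Occ {
  int32_t contig;
  int32_t pos;
  uint8_t orient;  // 0: forward k-mer is the canonical form, 1: reverse is
};

struct Match {
  int32_t qc, tc;   // query/target contig index (qc < tc)
  int32_t qp, tp;   // anchor start positions (forward strand of each contig)
  uint8_t strand;   // 0: '+', 1: '-'
};

bool match_order(const Match &a, const Match &b) {
  if (a.qc != b.qc) return a.qc < b.qc;
  if (a.tc != b.tc) return a.tc < b.tc;
  if (a.strand != b.strand) return a.strand < b.strand;
  int64_t da = a.strand ? (int64_t)a.qp + a.tp : (int64_t)a.qp - a.tp;
  int64_t db = b.strand ? (int64_t)b.qp + b.tp : (int64_t)b.qp - b.tp;
  if (da != db) return da < db;
  return a.qp < b.qp;
}

} // namespace

// Exact-anchor matcher: canonical k-mers occurring <= max_occ times in the
// assembly are shared anchors; maximal runs of consecutive co-diagonal
// anchors between two different contigs become alignment blocks. Only
// cross-contig matches are emitted (the query is always the contig with the
// smaller input index).
// [[Rcpp::export]]
DataFrame anchor_blocks_cpp(CharacterVector seqs, int k, int max_occ,
                            int min_block_len) {
  if (k < 2 || k > 31) stop("anchor_k must be between 2 and 31");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  const int nseq = (int)seqs.size();

  // pass 1: canonical k-mer occurrence counts
  std::unordered_map<uint64_t, uint32_t> occ_count;
  for (int s = 0; s < nseq; ++s) {
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
      if (++valid >= k) ++occ_count[std::min(fwd, rev)];
    }
  }

  // pass 2: positions of informative anchors (2..max_occ occurrences)
  std::unordered_map<uint64_t, std::vector<Occ>> index;
  for (int s = 0; s < nseq; ++s) {
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
        uint64_t can = std::min(fwd, rev);
        uint32_t cnt = occ_count[can];
        if (cnt >= 2 && cnt <= (uint32_t)max_occ) {
          index[can].push_back(
            {(int32_t)s, (int32_t)(i - k + 1), (uint8_t)(fwd == can ? 0 : 1)});
        }
      }
    }
  }

  // expand anchor co-occurrences into cross-contig matches
  std::vector<Match> matches;
  for (const auto &kv : index) {
    const std::vector<Occ> &v = kv.second;
    const size_t m = v.size();
    for (size_t i = 0; i + 1 < m; ++i) {
      for (size_t j = i + 1; j < m; ++j) {
        if (v[i].contig == v[j].contig) continue;
        uint8_t strand = (v[i].orient == v[j].orient) ? 0 : 1;
        matches.push_back({v[i].contig, v[j].contig, v[i].pos, v[j].pos, strand});
      }
    }
  }
  std::sort(matches.begin(), matches.end(), match_order);

  // collapse maximal runs of consecutive co-diagonal anchors into blocks
  std::vector<int> bq, bt, bqs, bqe, bts, bte;
  std::vector<uint8_t> bstrand;
  size_t i = 0;
  const size_t M = matches.size();
  while (i < M) {
    size_t j = i;
    while (j + 1 < M) {
      const Match &a = matches[j], &b = matches[j + 1];
      if (a.qc != b.qc || a.tc != b.tc || a.strand != b.strand) break;
      if (b.qp != a.qp + 1) break;
      int expect_tp = a.strand ? a.tp - 1 : a.tp + 1;
      if (b.tp != expect_tp) break;
      ++j;
    }
    const Match &f = matches[i], &l = matches[j];
    int span = l.qp + k - f.qp;
    if (span >= min_block_len) {
      bq.push_back(f.qc + 1);  // 1-based contig indices for R
      bt.push_back(f.tc + 1);
      bqs.push_back(f.qp);
      bqe.push_back(l.qp + k);
      if (f.strand == 0) { bts.push_back(f.tp); bte.push_back(l.tp + k); }
      else               { bts.push_back(l.tp); bte.push_back(f.tp + k); }
      bstrand.push_back(f.strand);
    }
    i = j + 1;
  }

  const size_t B = bq.size();
  CharacterVector strand_out(B);
  for (size_t b = 0; b < B; ++b) strand_out[b] = bstrand[b] ? "-" : "+";
  return DataFrame::create(
    _["query"] = IntegerVector(bq.begin(), bq.end()),
    _["target"] = IntegerVector(bt.begin(), bt.end()),
    _["q_start"] = IntegerVector(bqs.begin(), bqs.end()),
    _["q_end"] = IntegerVector(bqe.begin(), bqe.end()),
    _["t_start"] = IntegerVector(bts.begin(), bts.end()),
    _["t_end"] = IntegerVector(bte.begin(), bte.end()),
    _["strand"] = strand_out);
}
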