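// Exact-match read mapper over extended atlas alleles.
//
// Because downstream counting only ever uses perfect alignments, mapping is
// exact substring search: a k-mer seed (default k = 31) retrieves candidate
// (sequence, offset) placements, each verified base-by-base. In
// quality-masked mode, read positions with base quality <= min_q act as
// wildcards; the seed is then taken from a window of k consecutive
// high-quality bases, falling back to a full scan when no such window
// exists (any true hit must match exactly on an all-high-quality window, so
// seeding stays complete).

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

struct MapIndex {
  std::vector<std::string> seqs;
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> table;
};

inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// 2-bit packed k-mer; returns false if window has a non-ACGT base
inline bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

// verify read against seq at offset; good[i] == false -> wildcard position
bool verify(const std::string& seq, const std::string& read,
            const std::vector<bool>& good, int offset) {
  if (offset < 0 || offset + (int)read.size() > (int)seq.size()) return false;
  for (size_t i = 0; i < read.size(); ++i)
    if (good[i] && seq[offset + i] != read[i]) return false;
  return true;
}

struct Hit { int seq_id; int offset; char strand; };

void collect_orientation(const MapIndex& idx, const std::string& read,
                         const std::vector<bool>& good, char strand,
                         std::vector<Hit>& hits) {
  const int n = (int)read.size();
  const int k = idx.k;
  // pick a seed window of k consecutive non-wildcard positions
  int seed_at = -1;
  if (n >= k) {
    int run = 0;
    for (int i = 0; i < n; ++i) {
      run = good[i] ? run + 1 : 0;
      if (run >= k) { seed_at = i - k + 1; break; }
    }
  }
  uint64_t key = 0;
  if (seed_at >= 0 && encode_kmer(read.data() + seed_at, k, key)) {
    auto it = idx.table.find(key);
    if (it == idx.table.end()) return;
    for (const auto& cand : it->second) {
      int offset = cand.second - seed_at;
      if (verify(idx.seqs[cand.first], read, good, offset))
        hits.push_back({cand.first, offset, strand});
    }
  } else {
    // short read or no clean seed window: exhaustive scan
    for (int s = 0; s < (int)idx.seqs.size(); ++s) {
      const int L = (int)idx.seqs[s].size();
      for (int off = 0; off + n <= L; ++off)
        if (verify(idx.seqs[s], read, good, off))
          hits.push_back({s, off, strand});
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".build_index_cpp")]]
SEXP build_index_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  MapIndex* idx = new MapIndex();
  idx->k = k;
  idx->seqs.reserve(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    idx->seqs.push_back(as<std::string>(seqs[i]));
  for (int s = 0; s < (int)idx->seqs.size(); ++s) {
    const std::string& sq = idx->seqs[s];
    for (int off = 0; off + k <= (int)sq.size(); ++off) {
      uint64_t key;
      if (encode_kmer(sq.data() + off, k, key))
        idx->table[key].push_back({s, off});
    }
  }
  XPtr<MapIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
DataFrame map_reads_cpp(SEXP index, CharacterVector reads,
                        CharacterVector quals, bool masked, int min_q) {
  XPtr<MapIndex> idx(index);
  std::vector<int> out_read, out_seq, out_off;
  std::vector<std::string> out_strand;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int n = (int)fwd.size();
    if (n == 0) continue;
    std::vector<bool> good(n, true);
    if (masked) {
      std::string q = as<std::string>(quals[r]);
      if ((int)q.size() != n) stop("quality/sequence length mismatch");
      for (int i = 0; i < n; ++i)
        good[i] = ((int)q[i] - 33 > min_q) && base2bits(fwd[i]) >= 0;
    }
    std::vector<Hit> hits;
    collect_orientation(*idx, fwd, good, '+', hits);
    std::string rev = revcomp(fwd);
    std::vector<bool> rgood(good.rbegin(), good.rend());
    collect_orientation(*idx, rev, rgood, '-', hits);
    for (const auto& h : hits) {
      out_read.push_back((int)r + 1);
      out_seq.push_back(h.seq_id + 1);
      out_off.push_back(h.offset);
      out_strand.push_back(std::string(1, h.strand));
    }
  }
  return DataFrame::create(_["read"] = out_read, _["seq"] = out_seq,
                           _["offset"] = out_off, _["strand"] = out_strand,
                           _["stringsAsFactors"] = false);
}
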