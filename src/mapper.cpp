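// k-mer seeded ungapped read mapper.
//
// The index stores every k-mer of every reference sequence on both strands
// (forward k-mer and its reverse complement, each pointing at the forward
// coordinate). Mapping seeds a read's k-mers on a stride, extends every
// candidate locus by full-length ungapped comparison, and keeps hits whose
// mismatch count stays within ceil(max_mismatch_frac * read_length).
// Any non-ACGT character (read or reference) counts as a mismatch.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;                 // uppercased references
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;
  // packed location: seq_id (<=2^30) << 34 | pos (<2^33) << 1 | strand
  static uint64_t pack(uint64_t seq, uint64_t pos, uint64_t strand) {
    return (seq << 34) | (pos << 1) | strand;
  }
  static void unpack(uint64_t v, uint64_t& seq, uint64_t& pos, uint64_t& strand) {
    strand = v & 1ULL;
    pos = (v >> 1) & ((1ULL << 33) - 1);
    seq = v >> 34;
  }
};

// rolling scan of valid k-mers (skipping windows containing non-ACGT)
template <typename F>
void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) f(i + 1 - k, fwd, rc);
  }
}

} // namespace

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->seqs.reserve(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (auto& ch : s) ch = (char)std::toupper((unsigned char)ch);
    idx->seqs.push_back(std::move(s));
  }
  for (size_t si = 0; si < idx->seqs.size(); ++si) {
    const std::string& s = idx->seqs[si];
    for_each_kmer(s, k, [&](size_t pos, uint64_t fwd, uint64_t rc) {
      idx->map[fwd].push_back(KmerIndex::pack(si, pos, 0));
      idx->map[rc].push_back(KmerIndex::pack(si, pos, 1));
    });
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_size(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return (int)idx->map.size();
}

// locations of one literal k-mer (forward-strand entries have strand 0,
// reverse-complement entries strand 1; positions are 0-based forward coords)
// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("k-mer length must equal index k");
  uint64_t code = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b < 0) stop("k-mer contains a non-ACGT character");
    code = (code << 2) | (uint64_t)b;
  }
  std::vector<int> seq, pos, strand;
  auto it = idx->map.find(code);
  if (it != idx->map.end()) {
    for (uint64_t v : it->second) {
      uint64_t s, p, st;
      KmerIndex::unpack(v, s, p, st);
      seq.push_back((int)s + 1);
      pos.push_back((int)p);
      strand.push_back((int)st);
    }
  }
  return DataFrame::create(_["seq"] = seq, _["pos"] = pos, _["strand"] = strand);
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xp, CharacterVector reads, int stride,
                        double max_mismatch_frac, double mismatch_penalty) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  std::vector<int> out_read, out_seq, out_start, out_strand, out_mm;
  std::vector<double> out_score;

  std::vector<uint64_t> cand;        // packed candidate (seq, start, strand)
  std::unordered_set<uint64_t> seen;

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    for (auto& ch : rd) ch = (char)std::toupper((unsigned char)ch);
    const int len = (int)rd.size();
    if (len < k) continue;
    const int mm_max = (int)std::ceil(max_mismatch_frac * len - 1e-9);

    // seed offsets on the stride grid, always including the final window
    cand.clear();
    seen.clear();
    std::vector<int> offsets;
    for (int o = 0; o + k <= len; o += stride) offsets.push_back(o);
    if (offsets.empty() || offsets.back() != len - k) offsets.push_back(len - k);

    for (int o : offsets) {
      // encode this k-mer; skip if it contains non-ACGT
      uint64_t code = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int b = base_code(rd[o + j]);
        if (b < 0) { ok = false; break; }
        code = (code << 2) | (uint64_t)b;
      }
      if (!ok) continue;
      auto it = idx->map.find(code);
      if (it == idx->map.end()) continue;
      for (uint64_t v : it->second) {
        uint64_t s, p, st;
        KmerIndex::unpack(v, s, p, st);
        long long start = (st == 0)
          ? (long long)p - o
          : (long long)p - (len - k - o);
        if (start < 0) continue;
        if (start + len > (long long)idx->seqs[s].size()) continue;
        uint64_t key = KmerIndex::pack(s, (uint64_t)start, st);
        if (seen.insert(key).second) cand.push_back(key);
      }
    }

    if (cand.empty()) continue;
    std::string rc;
    bool have_rc = false;

    for (uint64_t key : cand) {
      uint64_t s, p, st;
      KmerIndex::unpack(key, s, p, st);
      const std::string& ref = idx->seqs[s];
      const std::string* q = &rd;
      if (st == 1) {
        if (!have_rc) {
          rc.resize(len);
          for (int j = 0; j < len; ++j) {
            int b = base_code(rd[len - 1 - j]);
            rc[j] = (b < 0) ? 'N' : "TGCA"[b];
          }
          have_rc = true;
        }
        q = &rc;
      }
      int mm = 0;
      for (int j = 0; j < len && mm <= mm_max; ++j) {
        char a = (*q)[j], b = ref[p + j];
        if (a != b || base_code(a) < 0 || base_code(b) < 0) ++mm;
      }
      if (mm > mm_max) continue;
      out_read.push_back((int)r + 1);
      out_seq.push_back((int)s + 1);
      out_start.push_back((int)p);
      out_strand.push_back((int)st);
      out_mm.push_back(mm);
      out_score.push_back((double)(len - mm) - mismatch_penalty * mm);
    }
  }

  return DataFrame::create(
    _["read"] = out_read, _["seq"] = out_seq, _["start"] = out_start,
    _["strand"] = out_strand, _["mismatches"] = out_mm, _["score"] = out_score);
}
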