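#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// 2-bit base codes; -1 for non-ACGT
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Encode s[pos, pos+k) as a 2k-bit integer; false if any non-ACGT base.
static bool encode_kmer(const char* s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static uint64_t revcomp_kmer(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (v & 3));
    v >>= 2;
  }
  return r;
}

// Kept length per read under the sliding-window quality rule:
// scan 5'->3' in windows of `window` bases (step 1); truncate at the start of
// the first window whose mean quality < threshold. Reads shorter than the
// window are judged on their full length.
// [[Rcpp::export]]
IntegerVector cpp_trim_lengths(CharacterVector quals, int window,
                               double threshold, int phred_offset) {
  int n = quals.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char* q = CHAR(STRING_ELT(quals, r));
    int len = LENGTH(STRING_ELT(quals, r));
    int w = window < len ? window : len;
    if (len == 0) { out[r] = 0; continue; }
    double limit = threshold * w;
    double sum = 0;
    for (int i = 0; i < w; ++i) sum += q[i] - phred_offset;
    int keep = len;
    if (sum < limit) {
      keep = 0;
    } else {
      for (int start = 1; start + w <= len; ++start) {
        sum += (q[start + w - 1] - phred_offset) - (q[start - 1] - phred_offset);
        if (sum < limit) { keep = start; break; }
      }
    }
    out[r] = keep;
  }
  return out;
}

// Fraction of each read's k-mers found exactly in the host sequence on either
// strand. NA for reads with no complete k-mer.
// [[Rcpp::export]]
NumericVector cpp_host_kmer_frac(CharacterVector reads, std::string host, int k) {
  std::unordered_set<uint64_t> idx;
  int hl = (int)host.size();
  idx.reserve(hl > k ? hl : 16);
  const char* h = host.c_str();
  for (int i = 0; i + k <= hl; ++i) {
    uint64_t v;
    if (encode_kmer(h, i, k, v)) idx.insert(v);
  }
  int n = reads.size();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = LENGTH(STRING_ELT(reads, r));
    int total = 0, hits = 0;
    for (int i = 0; i + k <= len; ++i) {
      uint64_t v;
      if (!encode_kmer(s, i, k, v)) continue;
      ++total;
      if (idx.count(v) || idx.count(revcomp_kmer(v, k))) ++hits;
    }
    out[r] = total == 0 ? NA_REAL : (double)hits / total;
  }
  return out;
}

// Reference k-mer index reused across samples of the same species.
struct RefIndex {
  std::string seq;
  int k;
  std::unordered_map<uint64_t, std::vector<int> > idx;
};

static void build_index(RefIndex& ri) {
  int L = (int)ri.seq.size();
  const char* rf = ri.seq.c_str();
  ri.idx.reserve(L);
  for (int i = 0; i + ri.k <= L; ++i) {
    uint64_t v;
    if (encode_kmer(rf, i, ri.k, v)) ri.idx[v].push_back(i);
  }
}

// [[Rcpp::export]]
SEXP cpp_build_ref_index(std::string ref, int k) {
  XPtr<RefIndex> p(new RefIndex(), true);
  p->seq = ref;
  p->k = k;
  build_index(*p);
  return p;
}

// FNV-1a hash of a string, folded into a double-exact integer (< 2^53);
// used only as a cache key alongside species id and length.
// [[Rcpp::export]]
double cpp_seq_hash(std::string s) {
  uint64_t h = 1469598103934665603ULL;
  for (char c : s) {
    h ^= (uint64_t)(unsigned char)c;
    h *= 1099511628211ULL;
  }
  return (double)(h >> 12);
}

// Assemble reads from 0-based start positions, then apply substitution
// errors: err_at holds 0-based linear base indices (read-major: read r, base
// i -> r * read_length + i) and err_shift a 1..3 step around the A<C<G<T
// cycle.
// [[Rcpp::export]]
CharacterVector cpp_make_reads(std::string genome, IntegerVector starts,
                               int read_length, IntegerVector err_at,
                               IntegerVector err_shift) {
  static const char BASE[4] = {'A', 'C', 'G', 'T'};
  int n = starts.size();
  std::vector<std::string> out(n);
  for (int r = 0; r < n; ++r)
    out[r] = genome.substr(starts[r], read_length);
  for (int e = 0; e < err_at.size(); ++e) {
    long at = err_at[e];
    int r = (int)(at / read_length), i = (int)(at % read_length);
    int c = base_code(out[r][i]);
    if (c >= 0) out[r][i] = BASE[(c + err_shift[e]) % 4];
  }
  return wrap(out);
}

// Exact-seed (k-mer) placement with ungapped verification. Seeds are tried at
// offsets 0, k, 2k, ... within the read; every candidate placement implied by
// a seed hit is verified over the full read and the placement with the fewest
// mismatches (<= max_mismatch_frac * read length) wins; ties go to the
// leftmost position. Forward strand only. Returns base counts per reference
// position (columns A,C,G,T), the 0-based placement per read (NA when
// unplaced), and the number of reads longer than the reference (ignored).
// [[Rcpp::export]]
List cpp_map_reads(SEXP index, CharacterVector reads, double max_mismatch_frac) {
  XPtr<RefIndex> ri(index);
  const std::string& ref = ri->seq;
  int k = ri->k;
  std::unordered_map<uint64_t, std::vector<int> >& idx = ri->idx;
  int L = (int)ref.size();
  const char* rf = ref.c_str();
  int n = reads.size();
  IntegerMatrix counts(L, 4);
  IntegerVector pos(n);
  int n_too_long = 0;
  std::vector<int> cand;
  for (int r = 0; r < n; ++r) {
    pos[r] = NA_INTEGER;
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = LENGTH(STRING_ELT(reads, r));
    if (len > L) { ++n_too_long; continue; }
    if (len < k) continue;
    int max_mm = (int)(max_mismatch_frac * len);
    int best_pos = -1, best_mm = max_mm + 1;
    cand.clear();
    for (int off = 0; off + k <= len; off += k) {
      uint64_t v;
      if (!encode_kmer(s, off, k, v)) continue;
      auto it = idx.find(v);
      if (it == idx.end()) continue;
      for (int hit : it->second) {
        int p = hit - off;
        if (p < 0 || p + len > L) continue;
        bool seen = false;
        for (int c : cand) if (c == p) { seen = true; break; }
        if (seen) continue;
        cand.push_back(p);
        int mm = 0;
        for (int i = 0; i < len && mm < best_mm; ++i)
          if (s[i] != rf[p + i]) ++mm;
        if (mm < best_mm || (mm == best_mm && p < best_pos)) {
          best_mm = mm;
          best_pos = p;
        }
      }
    }
    if (best_pos >= 0 && best_mm <= max_mm) {
      pos[r] = best_pos;
      for (int i = 0; i < len; ++i) {
        int c = base_code(s[i]);
        if (c >= 0) ++counts(best_pos + i, c);
      }
    }
  }
  return List::create(_["counts"] = counts, _["pos"] = pos,
                      _["n_too_long"] = n_too_long);
}

// Majority-base consensus over a pileup count matrix (columns A,C,G,T).
// Returns 1-based base codes (1=A..4=T) with NA where depth < min_depth;
// ties resolved toward the earlier base in A<C<G<T order.
// [[Rcpp::export]]
IntegerVector cpp_consensus(IntegerMatrix counts, int min_depth) {
  int L = counts.nrow();
  IntegerVector out(L);
  for (int i = 0; i < L; ++i) {
    int depth = counts(i, 0) + counts(i, 1) + counts(i, 2) + counts(i, 3);
    if (depth < min_depth) { out[i] = NA_INTEGER; continue; }
    int best = 0;
    for (int b = 1; b < 4; ++b)
      if (counts(i, b) > counts(i, best)) best = b;
    out[i] = best + 1;
  }
  return out;
}
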