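// Canonical k-mer hashing and sequence simulation kernels.
//
// Hashes are 53-bit values stored in R doubles so they remain exact
// integers on the R side (no 64-bit integer type in base R). A k-mer is
// 2-bit encoded with the first base in the most significant bits, so the
// numeric order of codes equals lexicographic order of the sequences and
// the canonical form (min of forward and reverse complement) can be taken
// on the codes directly. The code is mixed with a user seed through the
// splitmix64 finalizer, then masked to 53 bits. k is limited to 31 so the
// encoding fits one 64-bit word.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static const uint64_t MASK53 = (1ULL << 53) - 1;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double hash_code(uint64_t code, uint64_t seed) {
  return static_cast<double>(splitmix64(code ^ seed) & MASK53);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Emit canonical k-mer hashes of one sequence into out; windows containing
// any non-ACGT character are skipped.
static void stream_hashes(const char* s, size_t n, int k, uint64_t seed,
                          std::vector<double>& out) {
  if (static_cast<size_t>(k) > n) return;
  const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int rc_shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int filled = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { filled = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | static_cast<uint64_t>(c)) & kmask;
    rev = (rev >> 2) | (static_cast<uint64_t>(3 - c) << rc_shift);
    if (++filled >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      out.push_back(hash_code(canon, seed));
    }
  }
}

static uint64_t as_seed(double seed) {
  return static_cast<uint64_t>(static_cast<int64_t>(seed));
}

// [[Rcpp::export]]
NumericVector cpp_kmer_hashes(std::string seq, int k, double seed) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::vector<double> out;
  stream_hashes(seq.c_str(), seq.size(), k, as_seed(seed), out);
  return NumericVector(out.begin(), out.end());
}

// Concatenated per-sequence hash streams plus the per-sequence counts, so
// large read sets can be hashed in one call.
// [[Rcpp::export]]
List cpp_kmer_hash_batch(CharacterVector seqs, int k, double seed) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  uint64_t sd = as_seed(seed);
  std::vector<double> out;
  IntegerVector nper(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    size_t before = out.size();
    const char* s = CHAR(STRING_ELT(seqs, i));
    stream_hashes(s, std::strlen(s), k, sd, out);
    nper[i] = static_cast<int>(out.size() - before);
  }
  return List::create(_["hashes"] = NumericVector(out.begin(), out.end()),
                      _["n_kmers"] = nper);
}

// Distinct canonical k-mer hashes across all sequences with their total
// occurrence counts, sorted ascending by hash.
// [[Rcpp::export]]
List cpp_kmer_counts(CharacterVector seqs, int k, double seed) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  uint64_t sd = as_seed(seed);
  std::unordered_map<double, int> counts;
  std::vector<double> buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    buf.clear();
    const char* s = CHAR(STRING_ELT(seqs, i));
    stream_hashes(s, std::strlen(s), k, sd, buf);
    for (double h : buf) ++counts[h];
  }
  std::vector<std::pair<double, int>> items(counts.begin(), counts.end());
  std::sort(items.begin(), items.end());
  NumericVector hashes(items.size());
  IntegerVector cnt(items.size());
  for (size_t i = 0; i < items.size(); ++i) {
    hashes[i] = items[i].first;
    cnt[i] = items[i].second;
  }
  return List::create(_["hash"] = hashes, _["count"] = cnt);
}

// 53-bit hash of an arbitrary byte string (used for parameter fingerprints
// in file headers).
// [[Rcpp::export]]
double cpp_hash_string(std::string s, double seed) {
  uint64_t h = as_seed(seed);
  for (char c : s) h = splitmix64(h ^ static_cast<uint64_t>(static_cast<unsigned char>(c)));
  return static_cast<double>(h & MASK53);
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Uniform random sequence; draws from R's RNG so results follow set.seed().
// [[Rcpp::export]]
std::string cpp_random_genome(int len) {
  std::string s(len, 'A');
  for (int i = 0; i < len; ++i) s[i] = BASES[static_cast<int>(unif_rand() * 4.0) & 3];
  return s;
}

// Independent per-base substitution to one of the three other bases with
// probability `rate`; non-ACGT characters are left untouched.
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double rate) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      int c = base_code(s[j]);
      if (c < 0) continue;
      if (unif_rand() < rate) {
        int shift = 1 + static_cast<int>(unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        s[j] = BASES[(c + shift) & 3];
      }
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t j = 0; j < r.size(); ++j) {
      int c = base_code(r[j]);
      r[j] = (c < 0) ? 'N' : BASES[3 - c];
    }
    out[i] = r;
  }
  return out;
}
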