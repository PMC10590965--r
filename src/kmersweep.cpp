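#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// DNA alphabet helpers
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return '\0';
  }
}

static inline char upper_base(char c) {
  return (c >= 'a' && c <= 'z') ? c - 32 : c;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(seqs[i]);
    size_t len = std::strlen(s);
    buf.assign(len, ' ');
    for (size_t j = 0; j < len; ++j) {
      char c = comp_base(upper_base(s[j]));
      if (c == '\0') {
        stop("invalid DNA character '%c' at position %d (sequence %d)",
             s[j], (int)(j + 1), (int)(i + 1));
      }
      buf[len - 1 - j] = c;
    }
    out[i] = buf;
  }
  return out;
}

// Canonical form of the k-mer starting at seq[pos]; returns false if the
// window contains a non-ACGT character. Writes into `out` (length k).
static inline bool canon_window(const char* seq, size_t pos, int k,
                                std::string& out) {
  // forward pass with validity check
  for (int j = 0; j < k; ++j) {
    char c = upper_base(seq[pos + j]);
    if (!is_acgt(c)) return false;
    out[j] = c;
  }
  // compare with reverse complement lexicographically, in place
  bool use_rc = false;
  for (int j = 0; j < k; ++j) {
    char rc = comp_base(out[k - 1 - j]);
    if (rc < out[j]) { use_rc = true; break; }
    if (rc > out[j]) { break; }
  }
  if (use_rc) {
    std::string tmp(out);
    for (int j = 0; j < k; ++j) out[j] = comp_base(tmp[k - 1 - j]);
  }
  return true;
}

// [[Rcpp::export(name = ".cpp_canonical_kmers")]]
List cpp_canonical_kmers(std::string seq, int k) {
  std::vector<int> pos;
  std::vector<std::string> kmers;
  if ((int)seq.size() >= k) {
    std::string w((size_t)k, ' ');
    size_t nwin = seq.size() - (size_t)k + 1;
    for (size_t i = 0; i < nwin; ++i) {
      if (canon_window(seq.c_str(), i, k, w)) {
        pos.push_back((int)i);
        kmers.push_back(w);
      }
    }
  }
  return List::create(_["pos"] = wrap(pos), _["kmer"] = wrap(kmers));
}

// [[Rcpp::export(name = ".cpp_canonicalize")]]
CharacterVector cpp_canonicalize(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(kmers[i]);
    size_t len = std::strlen(s);
    std::string w(len, ' ');
    if (!canon_window(s, 0, (int)len, w)) {
      stop("k-mer %d contains a non-ACGT character: '%s'", (int)(i + 1), s);
    }
    out[i] = w;
  }
  return out;
}

// ---------------------------------------------------------------------------
// 64-bit string hashing (FNV-1a with a splitmix64 finalizer), seeded so a
// double-hashing scheme g1 + i*g2 can be derived from two seeds.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t hash_str(const char* s, size_t n, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL ^ splitmix64(seed);
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint8_t)s[i];
    h *= 1099511628211ULL;
  }
  return splitmix64(h);
}

// ---------------------------------------------------------------------------
// Bloom filter
// ---------------------------------------------------------------------------

struct Bloom {
  std::vector<uint8_t> bits;  // m bits, byte-packed
  uint64_t m;                 // number of bits
  int h;                      // number of hash functions
  int k;                      // k-mer length this filter indexes
  double capacity;
  double error_rate;
  double inserted;            // number of insert calls (elements)

  inline void positions(const char* s, size_t n, uint64_t* out) const {
    uint64_t g1 = hash_str(s, n, 0x51ED270B9F1D2CC1ULL);
    uint64_t g2 = hash_str(s, n, 0xA24BAED4963EE407ULL);
    if (g2 % m == 0) g2 = 1;  // keep the stride non-degenerate
    for (int i = 0; i < h; ++i) out[i] = (g1 + (uint64_t)i * g2) % m;
  }
  inline void insert1(const char* s, size_t n) {
    uint64_t p[64];
    positions(s, n, p);
    for (int i = 0; i < h; ++i) bits[p[i] >> 3] |= (uint8_t)(1u << (p[i] & 7));
  }
  inline bool query1(const char* s, size_t n) const {
    uint64_t p[64];
    positions(s, n, p);
    for (int i = 0; i < h; ++i)
      if (!(bits[p[i] >> 3] & (uint8_t)(1u << (p[i] & 7)))) return false;
    return true;
  }
};

typedef XPtr<Bloom> BloomPtr;

// [[Rcpp::export(name = ".cpp_bf_new")]]
SEXP cpp_bf_new(double m_bits, int num_hashes, int k, double capacity,
                double error_rate) {
  if (num_hashes < 1 || num_hashes > 64) stop("number of hash functions out of range");
  Bloom* bf = new Bloom();
  bf->m = (uint64_t)m_bits;
  bf->h = num_hashes;
  bf->k = k;
  bf->capacity = capacity;
  bf->error_rate = error_rate;
  bf->inserted = 0;
  uint64_t nbytes = (bf->m + 7) / 8;
  try {
    bf->bits.assign(nbytes, 0);
  } catch (std::bad_alloc&) {
    delete bf;
    stop("cannot allocate bit array of %.0f bytes; reduce capacity or raise error rate",
         (double)nbytes);
  }
  return BloomPtr(bf, true);
}

// [[Rcpp::export(name = ".cpp_bf_insert")]]
void cpp_bf_insert(SEXP xp, CharacterVector kmers) {
  BloomPtr bf(xp);
  R_xlen_t n = kmers.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(kmers[i]);
    size_t len = std::strlen(s);
    if ((int)len != bf->k)
      stop("k-mer %d has length %d but the filter was built for k=%d",
           (int)(i + 1), (int)len, bf->k);
    bf->insert1(s, len);
  }
  bf->inserted += (double)n;
}

// [[Rcpp::export(name = ".cpp_bf_query")]]
LogicalVector cpp_bf_query(SEXP xp, CharacterVector kmers) {
  BloomPtr bf(xp);
  R_xlen_t n = kmers.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(kmers[i]);
    size_t len = std::strlen(s);
    if ((int)len != bf->k)
      stop("k-mer %d has length %d but the filter was built for k=%d",
           (int)(i + 1), (int)len, bf->k);
    out[i] = bf->query1(s, len);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_bf_params")]]
List cpp_bf_params(SEXP xp) {
  BloomPtr bf(xp);
  return List::create(_["m"] = (double)bf->m, _["num_hashes"] = bf->h,
                      _["k"] = bf->k, _["capacity"] = bf->capacity,
                      _["error_rate"] = bf->error_rate,
                      _["inserted"] = bf->inserted);
}

// [[Rcpp::export(name = ".cpp_bf_bits")]]
RawVector cpp_bf_bits(SEXP xp) {
  BloomPtr bf(xp);
  RawVector out((R_xlen_t)bf->bits.size());
  if (bf->bits.size() > 0)
    std::memcpy(RAW(out), bf->bits.data(), bf->bits.size());
  return out;
}

// [[Rcpp::export(name = ".cpp_bf_set_state")]]
void cpp_bf_set_state(SEXP xp, RawVector bits, double inserted) {
  BloomPtr bf(xp);
  if ((uint64_t)bits.size() != bf->bits.size())
    stop("bit payload has %d bytes, expected %d",
         (int)bits.size(), (int)bf->bits.size());
  std::memcpy(bf->bits.data(), RAW(bits), bf->bits.size());
  bf->inserted = inserted;
}

// ---------------------------------------------------------------------------
// Exact k-mer set (hash set of canonical k-mer strings)
// ---------------------------------------------------------------------------

struct ExactSet {
  std::unordered_set<std::string> s;
  int k;
};

typedef XPtr<ExactSet> SetPtr;

// [[Rcpp::export(name = ".cpp_set_new")]]
SEXP cpp_set_new(CharacterVector kmers, int k) {
  ExactSet* es = new ExactSet();
  es->k = k;
  R_xlen_t n = kmers.size();
  es->s.reserve((size_t)n * 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(kmers[i]);
    if ((int)std::strlen(s) != k)
      { delete es; stop("k-mer %d does not have length k=%d", (int)(i + 1), k); }
    es->s.insert(s);
  }
  return SetPtr(es, true);
}

// [[Rcpp::export(name = ".cpp_set_contains")]]
LogicalVector cpp_set_contains(SEXP xp, CharacterVector kmers) {
  SetPtr es(xp);
  R_xlen_t n = kmers.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = es->s.count(CHAR(kmers[i])) > 0;
  return out;
}

// [[Rcpp::export(name = ".cpp_set_members")]]
CharacterVector cpp_set_members(SEXP xp) {
  SetPtr es(xp);
  CharacterVector out((R_xlen_t)es->s.size());
  R_xlen_t i = 0;
  for (const auto& w : es->s) out[i++] = w;
  return out;
}

// [[Rcpp::export(name = ".cpp_set_size")]]
double cpp_set_size(SEXP xp) {
  SetPtr es(xp);
  return (double)es->s.size();
}

// ---------------------------------------------------------------------------
// Two-pass classifier kernels. Membership is either a Bloom filter (pass 1)
// or an exact set (pass 2 / oracle runs); `is_bloom` selects the backend.
// ---------------------------------------------------------------------------

static inline bool memb_query(SEXP xp, bool is_bloom, const std::string& w) {
  if (is_bloom) {
    Bloom* bf = (Bloom*)R_ExternalPtrAddr(xp);
    return bf->query1(w.c_str(), w.size());
  }
  ExactSet* es = (ExactSet*)R_ExternalPtrAddr(xp);
  return es->s.count(w) > 0;
}

// Pass 1: a read is an anchor iff two valid windows at adjacent start
// positions both match the membership structure.
// [[Rcpp::export(name = ".cpp_find_anchors")]]
LogicalVector cpp_find_anchors(CharacterVector seqs, SEXP xp, bool is_bloom,
                               int k) {
  R_xlen_t n = seqs.size();
  LogicalVector out(n);
  std::string w((size_t)k, ' ');
  for (R_xlen_t r = 0; r < n; ++r) {
    const char* s = CHAR(seqs[r]);
    size_t len = std::strlen(s);
    bool anchor = false;
    if ((int)len >= k + 1) {
      size_t nwin = len - (size_t)k + 1;
      bool prev_hit = false;
      for (size_t i = 0; i < nwin; ++i) {
        bool hit = false;
        if (canon_window(s, i, k, w)) hit = memb_query(xp, is_bloom, w);
        if (hit && prev_hit) { anchor = true; break; }
        prev_hit = hit;
      }
    }
    out[r] = anchor;
  }
  return out;
}

// Harvest the union of canonical k-mers over flagged reads into a new
// exact set.
// [[Rcpp::export(name = ".cpp_collect_kmers")]]
SEXP cpp_collect_kmers(CharacterVector seqs, LogicalVector flags, int k) {
  ExactSet* es = new ExactSet();
  es->k = k;
  std::string w((size_t)k, ' ');
  R_xlen_t n = seqs.size();
  for (R_xlen_t r = 0; r < n; ++r) {
    if (!flags[r]) continue;
    const char* s = CHAR(seqs[r]);
    size_t len = std::strlen(s);
    if ((int)len < k) continue;
    size_t nwin = len - (size_t)k + 1;
    for (size_t i = 0; i < nwin; ++i)
      if (canon_window(s, i, k, w)) es->s.insert(w);
  }
  return SetPtr(es, true);
}

// Pass 2 statistics: per read, the number of valid k-mer windows and the
// number of those found in the anchor set.
// [[Rcpp::export(name = ".cpp_anchor_stats")]]
List cpp_anchor_stats(CharacterVector seqs, SEXP xp, int k) {
  SetPtr es(xp);
  R_xlen_t n = seqs.size();
  IntegerVector n_valid(n), n_hit(n);
  std::string w((size_t)k, ' ');
  for (R_xlen_t r = 0; r < n; ++r) {
    const char* s = CHAR(seqs[r]);
    size_t len = std::strlen(s);
    int nv = 0, nh = 0;
    if ((int)len >= k) {
      size_t nwin = len - (size_t)k + 1;
      for (size_t i = 0; i < nwin; ++i) {
        if (canon_window(s, i, k, w)) {
          ++nv;
          if (es->s.count(w)) ++nh;
        }
      }
    }
    n_valid[r] = nv;
    n_hit[r] = nh;
  }
  return List::create(_["n_valid"] = n_valid, _["n_hit"] = n_hit);
}
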