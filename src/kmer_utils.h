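#ifndef BLOOMFINISH_KMER_UTILS_H
#define BLOOMFINISH_KMER_UTILS_H

#include <string>
#include <cstdint>
#include <cctype>

inline char upbase(char c) {
  return static_cast<char>(std::toupper(static_cast<unsigned char>(c)));
}

inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  }
  return 'N';
}

// Canonical form (lexicographic min of k-mer and its reverse complement) of
// the window s[j, j+k). Case-folds first; returns false if any base is not
// A/C/G/T after folding.
inline bool canonical_window(const char* s, long j, int k, std::string& out) {
  out.resize(k);
  thread_local std::string rc;
  rc.resize(k);
  for (int t = 0; t < k; ++t) {
    char c = upbase(s[j + t]);
    if (!is_acgt(c)) return false;
    out[t] = c;
    rc[k - 1 - t] = comp_base(c);
  }
  if (rc < out) out.swap(rc);
  return true;
}

inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Seeded 64-bit FNV-1a with splitmix finalizer; deterministic across
// platforms, which is the contract the pipeline needs.
inline std::uint64_t seeded_hash(const std::string& s, std::uint64_t seed) {
  std::uint64_t h = 1469598103934665603ULL ^ splitmix64(seed);
  for (char c : s) {
    h ^= static_cast<std::uint8_t>(c);
    h *= 1099511628211ULL;
  }
  return splitmix64(h);
}

#endif
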