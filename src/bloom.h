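#ifndef BLOOMFINISH_BLOOM_H
#define BLOOMFINISH_BLOOM_H

#include <vector>
#include <string>
#include <cstdint>
#include "kmer_utils.h"

// Plain bit-array Bloom filter over canonical k-mer strings.
struct BloomFilter {
  std::uint64_t m;           // size in bits
  int h;                     // number of hash functions
  int k;                     // k-mer length the filter is built for
  std::uint64_t seed;        // base seed; hash j uses seed + j
  std::uint64_t n_inserted;  // insertion calls attempted (monotone)
  std::vector<std::uint64_t> words;

  BloomFilter(std::uint64_t m_, int h_, int k_, std::uint64_t seed_)
    : m(m_), h(h_), k(k_), seed(seed_), n_inserted(0),
      words((m_ + 63) / 64, 0ULL) {}

  inline void set_bit(std::uint64_t i) { words[i >> 6] |= (1ULL << (i & 63)); }
  inline bool get_bit(std::uint64_t i) const {
    return (words[i >> 6] >> (i & 63)) & 1ULL;
  }

  inline void insert_canonical(const std::string& km) {
    for (int j = 0; j < h; ++j) set_bit(seeded_hash(km, seed + j) % m);
    ++n_inserted;
  }
  inline bool contains_canonical(const std::string& km) const {
    for (int j = 0; j < h; ++j)
      if (!get_bit(seeded_hash(km, seed + j) % m)) return false;
    return true;
  }

  std::uint64_t popcount() const {
    std::uint64_t n = 0;
    for (std::uint64_t w : words) {
      while (w) { w &= (w - 1); ++n; }
    }
    return n;
  }
};

#endif
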