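#include <Rcpp.h>
#include "bloom.h"

using namespace Rcpp;

static BloomFilter* get_bf(SEXP xp) {
  XPtr<BloomFilter> p(xp);
  if (!p) stop("invalid Bloom filter pointer");
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_bloom_new(double m, int h, int k, double seed) {
  if (m < 1) stop("Bloom filter size m must be >= 1 bit");
  if (h < 1) stop("hash count h must be >= 1");
  if (k < 1) stop("k must be >= 1");
  BloomFilter* bf =
    new BloomFilter((std::uint64_t)m, h, k, (std::uint64_t)seed);
  return XPtr<BloomFilter>(bf, true);
}

// [[Rcpp::export]]
List cpp_bloom_info(SEXP xp) {
  BloomFilter* bf = get_bf(xp);
  return List::create(_["m"] = (double)bf->m, _["h"] = bf->h, _["k"] = bf->k,
                      _["n_inserted"] = (double)bf->n_inserted,
                      _["bits_set"] = (double)bf->popcount());
}

// [[Rcpp::export]]
void cpp_bloom_insert(SEXP xp, CharacterVector kmers) {
  BloomFilter* bf = get_bf(xp);
  std::string canon;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != bf->k)
      stop("k-mer length %d does not match filter k = %d", (int)s.size(),
           bf->k);
    if (!canonical_window(s.c_str(), 0, bf->k, canon))
      stop("k-mer contains a character outside ACGT: '%s'", s.c_str());
    bf->insert_canonical(canon);
  }
}

// [[Rcpp::export]]
LogicalVector cpp_bloom_contains(SEXP xp, CharacterVector kmers) {
  BloomFilter* bf = get_bf(xp);
  LogicalVector out(kmers.size());
  std::string canon;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != bf->k)
      stop("k-mer length %d does not match filter k = %d", (int)s.size(),
           bf->k);
    if (!canonical_window(s.c_str(), 0, bf->k, canon))
      stop("k-mer contains a character outside ACGT: '%s'", s.c_str());
    out[i] = bf->contains_canonical(canon);
  }
  return out;
}

// Insert every valid canonical k-mer of each sequence (all multiplicities).
// [[Rcpp::export]]
void cpp_bloom_insert_seqs(SEXP xp, CharacterVector seqs) {
  BloomFilter* bf = get_bf(xp);
  std::string canon;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    long n = (long)s.size();
    for (long j = 0; j + bf->k <= n; ++j)
      if (canonical_window(s.c_str(), j, bf->k, canon))
        bf->insert_canonical(canon);
  }
}

// Two-level cascading construction: an occurrence whose k-mer is already in
// level 1 goes into level 2, so level 2 holds (up to level-1 false
// positives) the k-mers of multiplicity >= 2. Returns the level-2 filter.
// [[Rcpp::export]]
SEXP cpp_build_cascading(CharacterVector reads, int k, double m, int h,
                         double seed) {
  if (m < 1) stop("Bloom filter size m must be >= 1 bit");
  if (h < 1) stop("hash count h must be >= 1");
  if (k < 1) stop("k must be >= 1");
  BloomFilter level1((std::uint64_t)m, h, k, (std::uint64_t)seed);
  BloomFilter* level2 =
    new BloomFilter((std::uint64_t)m, h, k, (std::uint64_t)seed);
  std::string canon;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    long n = (long)s.size();
    for (long j = 0; j + k <= n; ++j) {
      if (!canonical_window(s.c_str(), j, k, canon)) continue;
      if (level1.contains_canonical(canon)) level2->insert_canonical(canon);
      else level1.insert_canonical(canon);
    }
  }
  return XPtr<BloomFilter>(level2, true);
}
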