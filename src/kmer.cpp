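#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include "kmer_utils.h"

using namespace Rcpp;

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  std::string canon;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if (s.empty()) stop("k-mer must have length >= 1");
    if (!canonical_window(s.c_str(), 0, (int)s.size(), canon))
      stop("k-mer contains a character outside ACGT: '%s'", s.c_str());
    out[i] = canon;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string rc(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = upbase(s[s.size() - 1 - i]);
    rc[i] = is_acgt(c) ? comp_base(c) : 'N';
  }
  return rc;
}

// [[Rcpp::export]]
CharacterVector cpp_iter_kmers(std::string seq, int k) {
  if (k < 1) stop("k must be >= 1");
  std::vector<std::string> out;
  long n = (long)seq.size();
  std::string canon;
  for (long j = 0; j + k <= n; ++j) {
    if (canonical_window(seq.c_str(), j, k, canon)) out.push_back(canon);
  }
  return wrap(out);
}

// Exact canonical k-mer spectrum over a set of reads.
// [[Rcpp::export]]
List cpp_count_spectrum(CharacterVector reads, int k) {
  if (k < 1) stop("k must be >= 1");
  std::unordered_map<std::string, long> counts;
  std::string canon;
  double F1 = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    long n = (long)s.size();
    for (long j = 0; j + k <= n; ++j) {
      if (canonical_window(s.c_str(), j, k, canon)) {
        ++counts[canon];
        F1 += 1;
      }
    }
  }
  std::map<long, double> hist;
  for (const auto& kv : counts) hist[kv.second] += 1;
  double F0 = (double)counts.size();
  double f1 = 0;
  auto it = hist.find(1);
  if (it != hist.end()) f1 = it->second;
  std::vector<double> mult, cnt;
  for (const auto& kv : hist) {
    mult.push_back((double)kv.first);
    cnt.push_back(kv.second);
  }
  return List::create(_["multiplicity"] = wrap(mult), _["count"] = wrap(cnt),
                      _["F0"] = F0, _["F1"] = F1, _["f1"] = f1);
}
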