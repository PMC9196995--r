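#include <Rcpp.h>
#include <vector>
#include <string>
#include "bloom.h"

using namespace Rcpp;

// Bounded depth-first traversal of the implicit de Bruijn graph held in the
// Bloom filter. Extension starts from the terminal k-mer of the left flank;
// successors of a k-mer x are the (at most 4) k-mers x[2..k] + b whose
// canonical form is present. A path succeeds when its current k-mer equals
// the initial k-mer of the right flank; the returned strings are the bases
// spliced between the flanks (empty when the flanks already overlap).
// [[Rcpp::export]]
List cpp_traverse(SEXP xp, std::string left_flank, std::string right_flank,
                  double max_len, double max_branches, int max_paths) {
  XPtr<BloomFilter> p(xp);
  if (!p) stop("invalid Bloom filter pointer");
  const BloomFilter& bf = *p;
  const int k = bf.k;
  if ((long)left_flank.size() < k || (long)right_flank.size() < k)
    stop("flank-too-short");
  for (char& c : left_flank) c = upbase(c);
  for (char& c : right_flank) c = upbase(c);
  std::string start = left_flank.substr(left_flank.size() - k);
  std::string target = right_flank.substr(0, k);
  for (char c : start)
    if (!is_acgt(c)) stop("flank-too-short");
  for (char c : target)
    if (!is_acgt(c)) stop("flank-too-short");

  const char BASES[4] = {'A', 'C', 'G', 'T'};
  const long depth_cap = (long)max_len + k;  // extensions per path
  std::vector<std::string> paths;
  double expanded = 0;
  bool aborted = false;

  // frame: k-mer reached via `ext` extension bases
  struct Frame {
    std::string kmer;
    std::string ext;
  };
  std::vector<Frame> stack;
  stack.push_back({start, std::string()});

  std::string canon;
  while (!stack.empty()) {
    Frame fr = stack.back();
    stack.pop_back();
    expanded += 1;
    if (expanded > max_branches) { aborted = true; break; }
    if ((long)fr.ext.size() >= depth_cap) continue;
    // push successors in reverse so A is explored first
    for (int b = 3; b >= 0; --b) {
      std::string nxt = fr.kmer.substr(1) + BASES[b];
      if (!canonical_window(nxt.c_str(), 0, k, canon)) continue;
      if (!bf.contains_canonical(canon)) continue;
      std::string ext = fr.ext + BASES[b];
      if (nxt == target) {
        long t = (long)ext.size();
        paths.push_back(t > k ? ext.substr(0, t - k) : std::string());
        if ((int)paths.size() >= max_paths) {
          return List::create(_["paths"] = wrap(paths),
                              _["n_expanded"] = expanded,
                              _["aborted"] = false,
                              _["hit_max_paths"] = true);
        }
        continue;  // successful branch terminates here
      }
      stack.push_back({nxt, ext});
    }
  }
  return List::create(_["paths"] = wrap(paths), _["n_expanded"] = expanded,
                      _["aborted"] = aborted, _["hit_max_paths"] = false);
}
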