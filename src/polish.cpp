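#include <Rcpp.h>
#include <vector>
#include <string>
#include "bloom.h"

using namespace Rcpp;

namespace {

const char BASES[4] = {'A', 'C', 'G', 'T'};

struct Candidate {
  int kind;         // 0 = substitution, 1 = insertion, 2 = deletion
  std::string ref;  // replaced bases ("" for insertion)
  std::string alt;  // replacement ("" for deletion)
};

// Deterministic enumeration order: substitutions (ACGT order, skipping the
// current base), then insertions by length then lexicographic, then
// deletions by length. Deletions are clipped at the contig end and must
// remove plain uppercase ACGT only (N and soft-masked bases are never
// edited).
void enumerate_candidates(const std::string& seq, long i, int max_indel,
                          std::vector<Candidate>& out) {
  out.clear();
  long n = (long)seq.size();
  char cur = upbase(seq[i]);
  for (int b = 0; b < 4; ++b) {
    if (BASES[b] == cur) continue;
    out.push_back({0, std::string(1, cur), std::string(1, BASES[b])});
  }
  for (int L = 1; L <= max_indel; ++L) {
    long total = 1L << (2 * L);  // 4^L
    std::string ins(L, 'A');
    for (long code = 0; code < total; ++code) {
      long c = code;
      for (int t = L - 1; t >= 0; --t) {
        ins[t] = BASES[c & 3];
        c >>= 2;
      }
      out.push_back({1, "", ins});
    }
  }
  for (int L = 1; L <= max_indel && i + L <= n; ++L) {
    std::string del;
    bool ok = true;
    for (int t = 0; t < L; ++t) {
      char c = seq[i + t];
      if (!is_acgt(c)) { ok = false; break; }  // uppercase ACGT only
      del.push_back(c);
    }
    if (!ok) break;
    out.push_back({2, del, ""});
  }
}

// Fraction of k-mers covering the edited locus that are present in the
// filter after applying the candidate at position i. Windows truncated at
// contig ends (or containing non-ACGT) shrink the denominator.
double support_of(const std::string& seq, long i, const std::string& ref,
                  const std::string& alt, const BloomFilter& bf) {
  int k = bf.k;
  long n = (long)seq.size();
  long lo = std::max(0L, i - (k - 1));
  long hi = std::min(n, i + (long)ref.size() + (k - 1));
  std::string local = seq.substr(lo, hi - lo);
  long ri = i - lo;
  local = local.substr(0, ri) + alt + local.substr(ri + ref.size());
  long seg_l = ri;
  long seg_r = ri + (long)alt.size();
  long jlo, jhi;
  if (alt.empty()) {
    // deletion: windows spanning the junction
    jlo = seg_l - k + 1;
    jhi = seg_l - 1;
  } else {
    jlo = seg_l - k + 1;
    jhi = seg_r - 1;
  }
  jlo = std::max(jlo, 0L);
  jhi = std::min(jhi, (long)local.size() - k);
  int evaluated = 0, present = 0;
  std::string canon;
  for (long j = jlo; j <= jhi; ++j) {
    if (!canonical_window(local.c_str(), j, k, canon)) continue;
    ++evaluated;
    if (bf.contains_canonical(canon)) ++present;
  }
  return evaluated ? (double)present / evaluated : 0.0;
}

BloomFilter* get_bf(SEXP xp) {
  XPtr<BloomFilter> p(xp);
  if (!p) stop("invalid Bloom filter pointer");
  return p.get();
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_enumerate_edits(std::string seq, double i0, int max_indel) {
  long i = (long)i0;
  if (i < 0 || i >= (long)seq.size()) stop("position out of range");
  if (max_indel < 0) stop("max_indel must be >= 0");
  std::vector<Candidate> cands;
  enumerate_candidates(seq, i, max_indel, cands);
  CharacterVector kind(cands.size()), ref(cands.size()), alt(cands.size());
  const char* KINDS[3] = {"substitution", "insertion", "deletion"};
  for (size_t t = 0; t < cands.size(); ++t) {
    kind[t] = KINDS[cands[t].kind];
    ref[t] = cands[t].ref;
    alt[t] = cands[t].alt;
  }
  return DataFrame::create(_["kind"] = kind, _["ref"] = ref, _["alt"] = alt,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
double cpp_edit_support(std::string seq, double i0, std::string ref,
                        std::string alt, SEXP xp) {
  BloomFilter* bf = get_bf(xp);
  long i = (long)i0;
  if (i < 0 || i > (long)seq.size()) stop("position out of range");
  if (i + (long)ref.size() > (long)seq.size())
    stop("candidate ref overruns the contig");
  return support_of(seq, i, ref, alt, *bf);
}

// Single-pass left-to-right polishing scan at one k. Returns the edited
// sequence (new soft-masked bases in lowercase), the accepted edits with
// 1-based positions on the pre-edit contig, and the count of newly
// lowercased bases.
// [[Rcpp::export]]
List cpp_polish_contig(std::string seq, SEXP xp, double trigger_frac,
                       double accept_frac, int max_indel) {
  BloomFilter* bfp = get_bf(xp);
  const BloomFilter& bf = *bfp;
  int k = bf.k;
  std::vector<double> positions, supports;
  std::vector<std::string> kinds, refs, alts;
  const char* KINDS[3] = {"substitution", "insertion", "deletion"};
  long masked = 0;
  long shift = 0;  // current minus pre-edit coordinate
  std::string canon;
  std::vector<Candidate> cands;

  if (k >= 1 && (long)seq.size() >= k) {
    long i = k - 1;
    while (i < (long)seq.size()) {
      char raw = seq[i];
      char c = upbase(raw);
      if (!is_acgt(c) || raw != c) { ++i; continue; }  // N or soft-masked
      long n = (long)seq.size();
      if (!canonical_window(seq.c_str(), i - k + 1, k, canon) ||
          bf.contains_canonical(canon)) {
        ++i;
        continue;
      }
      // absent fraction over all k-mers covering base i
      long lo = std::max(0L, i - k + 1), hi = std::min(i, n - k);
      int validc = 0, absent = 0;
      for (long j = lo; j <= hi; ++j) {
        if (!canonical_window(seq.c_str(), j, k, canon)) continue;
        ++validc;
        if (!bf.contains_canonical(canon)) ++absent;
      }
      if (validc == 0 || (double)absent / validc < trigger_frac) {
        ++i;
        continue;
      }
      enumerate_candidates(seq, i, max_indel, cands);
      double best = -1.0;
      long best_t = -1;
      for (size_t t = 0; t < cands.size(); ++t) {
        double s = support_of(seq, i, cands[t].ref, cands[t].alt, bf);
        if (s > best) { best = s; best_t = (long)t; }
        if (best >= 1.0) break;  // first-in-order wins ties; nothing can beat 1
      }
      if (best_t >= 0 && best >= accept_frac) {
        const Candidate& cd = cands[best_t];
        positions.push_back((double)(i - shift + 1));
        kinds.push_back(KINDS[cd.kind]);
        refs.push_back(cd.ref);
        alts.push_back(cd.alt);
        supports.push_back(best);
        long e;  // last index of the edited locus (junction - 1 for deletion)
        if (cd.kind == 0) {
          seq[i] = cd.alt[0];
          e = i;
        } else if (cd.kind == 1) {
          seq.insert(i, cd.alt);
          e = i + (long)cd.alt.size() - 1;
          shift += (long)cd.alt.size();
        } else {
          seq.erase(i, cd.ref.size());
          e = i - 1;
          shift -= (long)cd.ref.size();
        }
        // Resume at the first base past the edited locus. Re-edits of a
        // correctly fixed locus cannot trigger (its terminal k-mer is now
        // present); a second nearby error, by contrast, must stay visible.
        i = std::max(e + 1, (long)k - 1);
      } else {
        seq[i] = (char)std::tolower((unsigned char)raw);
        ++masked;
        ++i;
      }
    }
  }

  DataFrame edits = DataFrame::create(
      _["position"] = wrap(positions), _["kind"] = wrap(kinds),
      _["ref"] = wrap(refs), _["alt"] = wrap(alts),
      _["support"] = wrap(supports), _["stringsAsFactors"] = false);
  return List::create(_["seq"] = seq, _["edits"] = edits,
                      _["masked_bases"] = (double)masked);
}
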