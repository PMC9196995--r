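#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// Banded global alignment with unit mismatch and gap costs. The band covers
// diagonals j - i in [min(0, m-n) - extra, max(0, m-n) + extra]. When the
// optimal traceback touches the band edge the result may be inexact;
// `hit_boundary` reports that so the caller can widen the band and retry.
// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int extra) {
  const long n = (long)a.size();
  const long m = (long)b.size();
  const long delta = m - n;
  const long dlo = std::min(0L, delta) - extra;
  const long dhi = std::max(0L, delta) + extra;
  const long W = dhi - dlo + 1;
  if ((double)(n + 1) * (double)W > 4e9)
    stop("alignment band too large; sequences too divergent");

  const std::int32_t INF = std::numeric_limits<std::int32_t>::max() / 4;
  std::vector<std::int32_t> prev(W, INF), cur(W, INF);
  std::vector<std::uint8_t> tb((size_t)(n + 1) * W, 255);

  // row 0: only left moves
  for (long d = 0; d <= dhi; ++d) {
    long j = d;  // i = 0
    if (j > m) break;
    long idx = d - dlo;
    prev[idx] = (std::int32_t)j;
    tb[idx] = (j == 0) ? 3 : 2;  // 3 = origin
  }
  for (long i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    std::uint8_t* tbrow = &tb[(size_t)i * W];
    long jlo = std::max(0L, i + dlo);
    long jhi = std::min(m, i + dhi);
    for (long j = jlo; j <= jhi; ++j) {
      long idx = j - i - dlo;
      std::int32_t best = INF;
      std::uint8_t op = 255;
      if (j >= 1 && prev[idx] < INF) {  // diagonal, same band index
        std::int32_t c = prev[idx] + (a[i - 1] == b[j - 1] ? 0 : 1);
        if (c < best) { best = c; op = 0; }
      }
      if (idx + 1 < W && prev[idx + 1] < INF) {  // up: consume a[i-1]
        std::int32_t c = prev[idx + 1] + 1;
        if (c < best) { best = c; op = 1; }
      }
      if (idx - 1 >= 0 && cur[idx - 1] < INF) {  // left: consume b[j-1]
        std::int32_t c = cur[idx - 1] + 1;
        if (c < best) { best = c; op = 2; }
      }
      cur[idx] = best;
      tbrow[idx] = op;
    }
    prev.swap(cur);
  }

  long idx_end = m - n - dlo;
  std::int32_t dist = prev[idx_end];
  if (dist >= INF) stop("no alignment within band");

  // traceback
  long i = n, j = m;
  double columns = 0, mismatches = 0, gap_openings = 0;
  std::uint8_t last_op = 0;
  bool hit_boundary = false;
  bool first = true;
  while (!(i == 0 && j == 0)) {
    long idx = j - i - dlo;
    if (idx == 0 || idx == W - 1) hit_boundary = true;
    std::uint8_t op = tb[(size_t)i * W + idx];
    if (op == 255 || op == 3) stop("traceback failed");
    columns += 1;
    if (op == 0) {
      if (a[i - 1] != b[j - 1]) mismatches += 1;
      --i; --j;
    } else if (op == 1) {
      if (first || last_op != 1) gap_openings += 1;
      --i;
    } else {
      if (first || last_op != 2) gap_openings += 1;
      --j;
    }
    last_op = op;
    first = false;
  }
  return List::create(_["distance"] = (double)dist, _["columns"] = columns,
                      _["mismatches"] = mismatches,
                      _["gap_openings"] = gap_openings,
                      _["hit_boundary"] = hit_boundary);
}
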