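#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Gapped adjacency extraction over the circular marker view of a genome.
//
// Genes are signed integers (id in 1..n_sym, O = o_id, never negative in a
// ring).  For an occurrence of the focal gene read positively, the written
// signed value s at k genes away on the requested side contributes
//   s   when 2k     < alpha   (its trailing extremity faces the focal gene)
//  -s   when 2k + 1 < alpha   (its leading extremity)
// Occurrences of the focal gene written negatively are read reversed with
// all signs flipped.  O is orientation-free: it is always contributed
// positively via its nearest extremity, and the odd-gap (-O) contribution
// is dropped.  With strict gap exclusion, a contribution whose k
// intervening genes include a copy of the focal or the contributed gene is
// suppressed.  The scan never wraps past the focal occurrence itself.

static void scan_occurrence(const std::vector<int> &ring, int i, int dir,
                            bool flip, int alpha, bool strict, int o_id,
                            int focal, std::vector<int> &out) {
  const int n = (int)ring.size();
  const int kmax = (alpha - 1) / 2;          // largest k with 2k < alpha
  for (int k = 0; k <= kmax && k <= n - 2; ++k) {
    int pos = ((i + dir * (k + 1)) % n + n) % n;
    int w = ring[pos];
    int sym = std::abs(w);
    if (strict) {
      // window = the k genes strictly between the occurrence and position
      // pos; the contribution is void if the focal or the contributed gene
      // sits inside it (the gap sequence ranges over +/-Sigma - {a, b})
      bool blocked = false;
      for (int j = 0; j < k; ++j) {
        int ps = std::abs(ring[((i + dir * (j + 1)) % n + n) % n]);
        if (ps == focal || ps == sym) { blocked = true; break; }
      }
      if (blocked) continue;
    }
    if (flip && sym != o_id) w = -w;
    if (sym == o_id) w = o_id;               // O read positively
    if (2 * k < alpha) out.push_back(w);
    if (2 * k + 1 < alpha && sym != o_id) out.push_back(-w);
  }
}

// [[Rcpp::export]]
List adj_multisets_cpp(List chroms, LogicalVector circular, IntegerVector query,
                       int side_right, int alpha, bool strict, int o_id) {
  const int nq = query.size();
  std::vector< std::vector<int> > res(nq);
  // rings
  std::vector< std::vector<int> > rings;
  for (int c = 0; c < chroms.size(); ++c) {
    IntegerVector ch = chroms[c];
    std::vector<int> ring(ch.begin(), ch.end());
    if (!circular[c]) ring.push_back(o_id);
    rings.push_back(ring);
  }
  for (int q = 0; q < nq; ++q) {
    int focal = query[q];
    std::vector<int> &out = res[q];
    for (size_t c = 0; c < rings.size(); ++c) {
      const std::vector<int> &ring = rings[c];
      const int n = (int)ring.size();
      if (n < 2) continue;                   // lone gene on a circular ring
      for (int i = 0; i < n; ++i) {
        if (std::abs(ring[i]) != focal) continue;
        bool neg = ring[i] < 0;              // O never negative
        // left scan runs against reading direction; a negative occurrence
        // reverses the reading direction and flips contributed signs
        int dir = (side_right != 0) ? (neg ? -1 : +1) : (neg ? +1 : -1);
        scan_occurrence(ring, i, dir, neg, alpha, strict, o_id, focal, out);
      }
    }
  }
  List ret(nq);
  for (int q = 0; q < nq; ++q) ret[q] = IntegerVector(res[q].begin(), res[q].end());
  return ret;
}
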