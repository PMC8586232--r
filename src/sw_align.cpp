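#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh local alignment with Waterman-Eggert style non-intersecting top-k:
// after reporting an alignment, its aligned residue pairs are masked (the
// diagonal transition through them is forbidden) and the DP is recomputed.
// gap_open is the cost of the first gap base, gap_ext of each further base.

// [[Rcpp::export]]
List sw_topk_cpp(std::string a, std::string b, int match, int mismatch,
                 int gap_open, int gap_ext, int k) {
  const int n = a.size(), m = b.size();
  const int NEG = -1000000000;
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  std::vector<char> mask((size_t)n * m, 0);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  List out;

  for (int rep = 0; rep < k; ++rep) {
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        int e = std::max(H[idx(i, j - 1)] - gap_open,
                         E[idx(i, j - 1)] - gap_ext);
        int f = std::max(H[idx(i - 1, j)] - gap_open,
                         F[idx(i - 1, j)] - gap_ext);
        E[idx(i, j)] = e;
        F[idx(i, j)] = f;
        int h = 0;
        if (!mask[(size_t)(i - 1) * m + (j - 1)]) {
          int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
          int d = H[idx(i - 1, j - 1)] + s;
          if (d > h) h = d;
        }
        if (e > h) h = e;
        if (f > h) h = f;
        H[idx(i, j)] = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (best <= 0) break;

    // traceback from (bi, bj), state 0 = H, 1 = E (gap in a), 2 = F
    int i = bi, j = bj, state = 0, matches = 0, cols = 0;
    std::string aa, ba;
    std::vector<std::pair<int, int> > pairs;
    while (true) {
      if (state == 0) {
        if (H[idx(i, j)] == 0) break;
        if (H[idx(i, j)] == E[idx(i, j)]) { state = 1; continue; }
        if (H[idx(i, j)] == F[idx(i, j)]) { state = 2; continue; }
        // diagonal
        pairs.push_back(std::make_pair(i, j));
        aa.push_back(a[i - 1]);
        ba.push_back(b[j - 1]);
        if (a[i - 1] == b[j - 1]) ++matches;
        ++cols;
        --i; --j;
      } else if (state == 1) {
        aa.push_back('-');
        ba.push_back(b[j - 1]);
        ++cols;
        if (E[idx(i, j)] == E[idx(i, j - 1)] - gap_ext) { --j; }
        else { --j; state = 0; }
      } else {
        aa.push_back(a[i - 1]);
        ba.push_back('-');
        ++cols;
        if (F[idx(i, j)] == F[idx(i - 1, j)] - gap_ext) { --i; }
        else { --i; state = 0; }
      }
    }
    std::reverse(aa.begin(), aa.end());
    std::reverse(ba.begin(), ba.end());
    for (size_t p = 0; p < pairs.size(); ++p)
      mask[(size_t)(pairs[p].first - 1) * m + (pairs[p].second - 1)] = 1;

    out.push_back(List::create(
        _["score"] = best, _["a_start"] = i + 1, _["a_end"] = bi,
        _["b_start"] = j + 1, _["b_end"] = bj, _["length"] = cols,
        _["matches"] = matches,
        _["identity"] = cols > 0 ? 100.0 * matches / cols : 0.0,
        _["a_aln"] = aa, _["b_aln"] = ba));
  }
  return out;
}
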