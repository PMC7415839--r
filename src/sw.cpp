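#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local (Smith-Waterman) alignment.
//
// A gap of length L costs open + extend * (L - 1): the opening penalty is
// charged on the first gap residue, the extension penalty thereafter.
//
// Determinism: the traceback prefers diagonal over up (residue of `a` against
// a gap) over left; among equal-scoring end cells the one with the smallest
// (row, column) pair, lexicographically, is chosen; inside a gap run the gap
// is closed as early as possible.
//
// Returns 0-based half-open coordinates of the aligned regions plus the two
// gapped row strings. A best score of 0 yields an empty alignment.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, IntegerMatrix mat,
                  CharacterVector alphabet, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int NEG = INT_MIN / 4;

  std::vector<int> lut(256, -1);
  for (int k = 0; k < alphabet.size(); ++k) {
    std::string s = as<std::string>(alphabet[k]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = k;
  }
  const int xi = lut[(unsigned char)'X'];
  if (xi < 0) stop("substitution matrix must contain an 'X' row/column");
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    int v = lut[(unsigned char)a[i]];
    ai[i] = v < 0 ? xi : v;
  }
  for (int j = 0; j < m; ++j) {
    int v = lut[(unsigned char)b[j]];
    bi[j] = v < 0 ? xi : v;
  }

  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  int best = 0, bi_ = 0, bj_ = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      // E: a[i-1] against a gap (move up); F: gap against b[j-1] (move left)
      int e = std::max(H[(i - 1) * W + j] - gap_open, E[(i - 1) * W + j] - gap_extend);
      int f = std::max(H[idx - 1] - gap_open, F[idx - 1] - gap_extend);
      int d = H[(i - 1) * W + (j - 1)] + mat(ai[i - 1], bi[j - 1]);
      int h = std::max(0, std::max(d, std::max(e, f)));
      E[idx] = e; F[idx] = f; H[idx] = h;
      if (h > best) { best = h; bi_ = i; bj_ = j; }  // strict '>' keeps smallest (i, j)
    }
  }

  std::string ra, rb;
  int i = bi_, j = bj_, state = 0;  // 0 = H, 1 = E (up), 2 = F (left)
  int a_end = bi_, b_end = bj_;
  if (best > 0) {
    while (true) {
      const int idx = i * W + j;
      if (state == 0) {
        if (H[idx] == 0) break;
        int d = H[(i - 1) * W + (j - 1)] + mat(ai[i - 1], bi[j - 1]);
        if (i > 0 && j > 0 && H[idx] == d) {
          ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
          --i; --j;
        } else if (H[idx] == E[idx]) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        const int up = (i - 1) * W + j;
        ra.push_back(a[i - 1]); rb.push_back('-');
        state = (E[idx] == H[up] - gap_open) ? 0 : 1;
        --i;
      } else {
        ra.push_back('-'); rb.push_back(b[j - 1]);
        state = (F[idx] == H[idx - 1] - gap_open) ? 0 : 2;
        --j;
      }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
  } else {
    i = 0; j = 0; a_end = 0; b_end = 0;
  }

  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = a_end,
                      _["b_start"] = j, _["b_end"] = b_end,
                      _["a_row"] = ra, _["b_row"] = rb);
}
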