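#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighbour offsets for 4- or 8-connectivity, row-major convention.
static inline int n_offsets(int connectivity) { return connectivity == 8 ? 8 : 4; }
static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Label connected components of 1-pixels. 0-pixels get label 0.
// Labels are assigned in row-major order of first visit, starting at 1.
// [[Rcpp::export]]
IntegerMatrix cc_label(const IntegerMatrix& bmap, int connectivity) {
  const int nr = bmap.nrow(), nc = bmap.ncol();
  const int noff = n_offsets(connectivity);
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (bmap(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx / nc, cc = idx % nc;
        for (int k = 0; k < noff; ++k) {
          int r2 = rr + DR[k], c2 = cc + DC[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (bmap(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 * nc + c2);
          }
        }
      }
    }
  }
  return lab;
}

// Border thinning that never merges segments.
//
// The foreground is labeled once; then repeated passes flip border
// (0) pixels back to foreground. Each pass fixes its frontier -- the
// 0-pixels with at least one foreground neighbour at pass start -- and
// scans it in row-major order, flipping a pixel iff all of its current
// foreground neighbours carry one common label; the flipped pixel
// adopts that label immediately, so a later pixel in the same pass sees
// the update. A pixel whose neighbours carry two distinct labels is
// where two segments would meet: it is never flipped, which is the
// non-merging guarantee. Terminates when a full pass flips nothing.
// [[Rcpp::export]]
IntegerMatrix thin_cpp(const IntegerMatrix& bmap, int connectivity) {
  const int nr = bmap.nrow(), nc = bmap.ncol();
  const int noff = n_offsets(connectivity);
  IntegerMatrix lab = cc_label(bmap, connectivity);
  std::vector<int> frontier;
  frontier.reserve(nr * nc / 4 + 1);
  bool changed = true;
  while (changed) {
    changed = false;
    frontier.clear();
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (lab(r, c) != 0) continue;
        bool has_fg = false;
        for (int k = 0; k < noff && !has_fg; ++k) {
          int r2 = r + DR[k], c2 = c + DC[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (lab(r2, c2) != 0) has_fg = true;
        }
        if (has_fg) frontier.push_back(r * nc + c);
      }
    }
    for (size_t i = 0; i < frontier.size(); ++i) {
      int idx = frontier[i];
      int r = idx / nc, c = idx % nc;
      if (lab(r, c) != 0) continue;  // flipped earlier this pass? cannot happen, kept for safety
      int seen = 0;
      bool conflict = false;
      for (int k = 0; k < noff; ++k) {
        int r2 = r + DR[k], c2 = c + DC[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int l2 = lab(r2, c2);
        if (l2 == 0) continue;
        if (seen == 0) seen = l2;
        else if (seen != l2) { conflict = true; break; }
      }
      if (seen != 0 && !conflict) {
        lab(r, c) = seen;
        changed = true;
      }
    }
  }
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = lab(r, c) != 0 ? 1 : 0;
  return out;
}
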