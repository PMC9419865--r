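#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen binary thinning. Input: logical/integer matrix (non-zero =
// foreground). Returns an integer matrix holding the 1-pixel-wide skeleton.
// Border pixels are treated as background neighbours.

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) != 0 ? 1 : 0;
}

// [[Rcpp::export]]
IntegerMatrix thin_zhang_suen(IntegerMatrix img) {
  IntegerMatrix m = clone(img);
  int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  kill.reserve(1024);
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!m(r, c)) continue;
          // neighbours P2..P9 clockwise from north (row-1)
          int p2 = px(m, r - 1, c),     p3 = px(m, r - 1, c + 1);
          int p4 = px(m, r,     c + 1), p5 = px(m, r + 1, c + 1);
          int p6 = px(m, r + 1, c),     p7 = px(m, r + 1, c - 1);
          int p8 = px(m, r,     c - 1), p9 = px(m, r - 1, c - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i)
          m(kill[i].first, kill[i].second) = 0;
      }
    }
  }
  return m;
}

// Crossing number per skeleton pixel: number of 0->1 transitions around the
// ordered 8-neighbour cycle (Hilditch). 1 = end point, 2 = line point,
// >= 3 = branch point. Robust to the staircase corners of diagonal lines,
// unlike a raw neighbour count. Returns -1 where the pixel is background.

// [[Rcpp::export]]
IntegerMatrix skeleton_crossing_number(IntegerMatrix skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!skel(r, c)) { out(r, c) = -1; continue; }
      int p[8] = { px(skel, r - 1, c),     px(skel, r - 1, c + 1),
                   px(skel, r,     c + 1), px(skel, r + 1, c + 1),
                   px(skel, r + 1, c),     px(skel, r + 1, c - 1),
                   px(skel, r,     c - 1), px(skel, r - 1, c - 1) };
      int a = 0;
      for (int i = 0; i < 8; ++i) a += (p[i] == 0 && p[(i + 1) % 8] == 1);
      out(r, c) = a;
    }
  return out;
}
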