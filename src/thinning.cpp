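#include <Rcpp.h>
using namespace Rcpp;

// Guo-Hall thinning (Guo & Hall 1989, CACM 32(3)) on a 0/1 matrix.
// Iterates the two sub-cycles until no pixel changes.  The result is an
// 8-connected, one-pixel-wide skeleton.  Blunt stroke ends are eroded by
// roughly half the stroke width; skeletonize_mask() in R restores them.
// [[Rcpp::export(name = ".guo_hall_thin")]]
LogicalMatrix guo_hall_thin(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // pad by 1 to avoid border checks
  std::vector<unsigned char> img((nr + 2) * (nc + 2), 0);
  auto at = [&](int r, int c) -> unsigned char& {
    return img[(size_t)(c) * (nr + 2) + r];
  };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      at(r + 1, c + 1) = mask(r, c) ? 1 : 0;

  std::vector<std::pair<int,int>> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      del.clear();
      for (int c = 1; c <= nc; ++c) {
        for (int r = 1; r <= nr; ++r) {
          if (!at(r, c)) continue;
          // neighbours clockwise from north
          const int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          const int p4 = at(r,     c + 1), p5 = at(r + 1, c + 1);
          const int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          const int p8 = at(r,     c - 1), p9 = at(r - 1, c - 1);
          const int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                        ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          const int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          const int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          const int N = N1 < N2 ? N1 : N2;
          const int m = (iter == 0) ? ((p6 | p7 | (!p9)) & p8)
                                    : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k)
          at(del[k].first, del[k].second) = 0;
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = at(r + 1, c + 1) != 0;
  return out;
}
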