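#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen morphological thinning of a binary mask (1 = foreground).
// Returns a 1-px-wide 8-connected skeleton. Implemented here because no
// installed imaging package exposes thinning.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img(clone(mask));
  std::vector<std::pair<int, int> > kill;
  bool changed = true;

  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img(r, c);
  };

  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < H; ++r) {
        for (int c = 0; c < W; ++c) {
          if (!img(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1), p4 = at(r, c + 1);
          int p5 = at(r + 1, c + 1), p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      for (size_t k = 0; k < kill.size(); ++k)
        img(kill[k].first, kill[k].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}
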