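// Zhang-Suen thinning of a binary mask.  Produces the 1-pixel-wide skeleton
// used by the endpoint-count morphometric.
#include <Rcpp.h>
#include <vector>

// Neighbourhood order P2..P9 clockwise from the pixel above:
//   P9 P2 P3
//   P8 P1 P4
//   P7 P6 P5
// [[Rcpp::export]]
Rcpp::IntegerMatrix thin_mask(Rcpp::IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<unsigned char> img((size_t)H * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      img[(size_t)j * H + i] = mask(i, j) != 0;

  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img[(size_t)c * H + r];
  };

  bool changed = true;
  std::vector<size_t> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!img[(size_t)c * H + r]) continue;
          const int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
                    p5 = at(r + 1, c + 1), p6 = at(r + 1, c),
                    p7 = at(r + 1, c - 1), p8 = at(r, c - 1),
                    p9 = at(r - 1, c - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int s = 0; s < 8; ++s)
            if (seq[s] == 0 && seq[s + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back((size_t)c * H + r);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t idx : kill) img[idx] = 0;
    }
  }

  Rcpp::IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = img[(size_t)j * H + i];
  return out;
}
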