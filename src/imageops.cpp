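#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling of the strictly-positive support of `mask`
// under 4- or 8-connectivity. Stack-based flood fill; labels are 1..k in
// raster order of each component's first pixel.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(NumericMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  int nn = connectivity;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) <= 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) > 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

static inline int at(const LogicalMatrix &m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen thinning to a 1-pixel-wide skeleton.
// [[Rcpp::export(name = ".zs_thin")]]
LogicalMatrix zs_thin(LogicalMatrix input) {
  int nr = input.nrow(), nc = input.ncol();
  LogicalMatrix img = clone(input);
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img(i, j)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = at(img, i - 1, j),     p3 = at(img, i - 1, j + 1);
          int p4 = at(img, i, j + 1),     p5 = at(img, i + 1, j + 1);
          int p6 = at(img, i + 1, j),     p7 = at(img, i + 1, j - 1);
          int p8 = at(img, i, j - 1),     p9 = at(img, i - 1, j - 1);
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
          kill.push_back(i + j * nr);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        img[kill[k]] = false;
    }
  }
  return img;
}
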