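// 3-D connected-component labelling of binary masks by breadth-first search
// under 6-, 18- or 26-connectivity, and nearest-point distances between
// boundary point sets (used by Hausdorff / ASSD).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List cc_label(IntegerVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  // neighbourhood offsets filtered by connectivity class
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  IntegerVector lab((size_t)nx * ny * nz);
  lab.attr("dim") = d;
  int ncomp = 0;
  std::vector<int> stack;
  for (R_xlen_t start = 0; start < mask.size(); ++start) {
    if (mask[start] == 0 || lab[start] != 0) continue;
    ++ncomp;
    lab[start] = ncomp;
    stack.clear();
    stack.push_back((int)start);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int z = v / (nx * ny), r = v % (nx * ny);
      const int y = r / nx, x = r % nx;
      for (size_t k = 0; k < ox.size(); ++k) {
        const int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const int w = xx + nx * (yy + ny * zz);
        if (mask[w] != 0 && lab[w] == 0) {
          lab[w] = ncomp;
          stack.push_back(w);
        }
      }
    }
  }
  return List::create(_["labels"] = lab, _["n"] = ncomp);
}

// For each row of A (points, mm), the Euclidean distance to its nearest
// row of B. Plain exhaustive scan: boundary sets are small at desk scale.
// [[Rcpp::export]]
NumericVector nearest_point_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int a = 0; a < d; ++a) {
        const double dd = A(i, a) - B(j, a);
        s += dd * dd;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
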