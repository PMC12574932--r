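#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Breadth-first connected-component labelling on a raster lattice.
// by_value = false: label components of non-zero, non-NA cells.
// by_value = true : cells additionally must share the same value to connect
//                   (used to split a stamped id map into coherent regions).
// Labels are 1..K in discovery (row-major) order; 0 = background.
// [[Rcpp::export]]
IntegerMatrix cc_label(NumericMatrix m, int connectivity, bool by_value) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> qr(nr * (size_t)nc), qc(nr * (size_t)nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  int nd = connectivity == 8 ? 8 : 4;
  int k = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = m(i, j);
      if (NumericMatrix::is_na(v) || v == 0.0 || lab(i, j) != 0) continue;
      ++k;
      int head = 0, tail = 0;
      qr[tail] = i; qc[tail] = j; ++tail;
      lab(i, j) = k;
      while (head < tail) {
        int r = qr[head], c = qc[head]; ++head;
        double vr = m(r, c);
        for (int d = 0; d < nd; ++d) {
          int r2 = r + dr[d], c2 = c + dc[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (lab(r2, c2) != 0) continue;
          double v2 = m(r2, c2);
          if (NumericMatrix::is_na(v2) || v2 == 0.0) continue;
          if (by_value && v2 != vr) continue;
          lab(r2, c2) = k;
          qr[tail] = r2; qc[tail] = c2; ++tail;
        }
      }
    }
  }
  lab.attr("n_components") = k;
  return lab;
}

// Count of 4-adjacencies between equal-valued cell pairs, per ordered class
// pair, double counted (each adjacency seen from both sides). Classes are the
// sorted unique non-NA values; returns a square matrix with that class order.
// Used by the contagion index.
// [[Rcpp::export]]
NumericMatrix adjacency_counts(NumericMatrix m, NumericVector classes) {
  int nr = m.nrow(), nc = m.ncol(), k = classes.size();
  NumericMatrix g(k, k);
  std::vector<double> cls(classes.begin(), classes.end());
  // map value -> index by linear scan (class counts are small)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = m(i, j);
      if (NumericMatrix::is_na(v)) continue;
      int a = -1;
      for (int t = 0; t < k; ++t) if (cls[t] == v) { a = t; break; }
      if (a < 0) continue;
      const int dr[4] = {-1, 0, 0, 1}, dc[4] = {0, -1, 1, 0};
      for (int d = 0; d < 4; ++d) {
        int r2 = i + dr[d], c2 = j + dc[d];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        double v2 = m(r2, c2);
        if (NumericMatrix::is_na(v2)) continue;
        int b = -1;
        for (int t = 0; t < k; ++t) if (cls[t] == v2) { b = t; break; }
        if (b >= 0) g(a, b) += 1.0;
      }
    }
  }
  return g;
}
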