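#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// symmetric (mirror) boundary: indices -1, -2, ... map to 0, 1, ...;
// n, n+1, ... map to n-1, n-2, ...
static inline int reflect_index(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

//' @name cc_local_stats
//' @title Local mean and standard deviation over a circular window
//' @description Computes, for every pixel, the mean and population standard
//'   deviation of intensities over a circular window of the given radius
//'   (offsets with dx^2 + dy^2 <= radius^2), with mirror (symmetric)
//'   padding at the image border. Backend for Phansalkar thresholding.
//' @param img numeric matrix.
//' @param radius integer window radius in pixels (>= 1).
//' @return list with matrices `mean` and `sd`.
//' @keywords internal
// [[Rcpp::export]]
List cc_local_stats(NumericMatrix img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  if (radius < 1) stop("radius must be >= 1");
  std::vector<int> di, dj;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { di.push_back(a); dj.push_back(b); }
  const int m = (int)di.size();
  NumericMatrix mu(nr, nc), sd(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0, s2 = 0.0;
      for (int k = 0; k < m; ++k) {
        int ii = i + di[k];
        int jj = j + dj[k];
        if (ii < 0 || ii >= nr) ii = reflect_index(ii, nr);
        if (jj < 0 || jj >= nc) jj = reflect_index(jj, nc);
        const double v = img(ii, jj);
        s += v;
        s2 += v * v;
      }
      const double mean = s / m;
      double var = s2 / m - mean * mean;
      if (var < 0.0) var = 0.0;  // numerical guard
      mu(i, j) = mean;
      sd(i, j) = std::sqrt(var);
    }
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}

//' @name cc_label8
//' @title 8-connectivity connected-component labeling
//' @description Labels connected sets of TRUE pixels using 8-connectivity
//'   (ImageJ particle convention). Labels are positive integers assigned in
//'   column-major scan order; background is 0.
//' @param mask logical matrix.
//' @return integer matrix of component labels.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix cc_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int cur = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) && lab(i, j) == 0) {
        ++cur;
        lab(i, j) = cur;
        stack.push_back(std::make_pair(i, j));
        while (!stack.empty()) {
          const std::pair<int, int> p = stack.back();
          stack.pop_back();
          for (int a = -1; a <= 1; ++a) {
            for (int b = -1; b <= 1; ++b) {
              const int ii = p.first + a, jj = p.second + b;
              if (ii >= 0 && ii < nr && jj >= 0 && jj < nc &&
                  mask(ii, jj) && lab(ii, jj) == 0) {
                lab(ii, jj) = cur;
                stack.push_back(std::make_pair(ii, jj));
              }
            }
          }
        }
      }
    }
  }
  return lab;
}
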