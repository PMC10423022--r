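#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Directed nearest-neighbour Euclidean distances from each row of X to the
// point set Y. Y is scanned in row-sorted order expanding outward from the
// query row, pruning once the squared row gap alone exceeds the best
// squared distance found so far; exact, and fast on skeleton-sized sets.
// [[Rcpp::export(name = ".nn_min_dist_cpp")]]
NumericVector nn_min_dist_cpp(IntegerMatrix X, IntegerMatrix Y) {
  const int nx = X.nrow(), ny = Y.nrow();
  NumericVector out(nx);
  if (ny == 0) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  // sort Y by row
  std::vector<int> ord(ny);
  for (int i = 0; i < ny; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return Y(a, 0) < Y(b, 0); });
  std::vector<int> yr(ny), yc(ny);
  for (int i = 0; i < ny; ++i) {
    yr[i] = Y(ord[i], 0);
    yc[i] = Y(ord[i], 1);
  }
  for (int i = 0; i < nx; ++i) {
    const int xr = X(i, 0), xc = X(i, 1);
    // first index with row >= xr
    int lo = (int)(std::lower_bound(yr.begin(), yr.end(), xr) - yr.begin());
    long long best = -1;
    int up = lo, down = lo - 1;
    while (up < ny || down >= 0) {
      if (up < ny) {
        long long dr = (long long)yr[up] - xr;
        if (best >= 0 && dr * dr > best) {
          up = ny;
        } else {
          long long dc = (long long)yc[up] - xc;
          long long d2 = dr * dr + dc * dc;
          if (best < 0 || d2 < best) best = d2;
          ++up;
        }
      }
      if (down >= 0) {
        long long dr = (long long)xr - yr[down];
        if (best >= 0 && dr * dr > best) {
          down = -1;
        } else {
          long long dc = (long long)yc[down] - xc;
          long long d2 = dr * dr + dc * dc;
          if (best < 0 || d2 < best) best = d2;
          --down;
        }
      }
    }
    out[i] = std::sqrt((double)best);
  }
  return out;
}
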