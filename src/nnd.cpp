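#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Grid-bucketed nearest-neighbor search. Behaviorally identical to the
// all-pairs computation: for every point returns the exact Euclidean
// distance to its nearest other point, ties broken by the lowest index.
// Expanding-ring search over grid cells; a ring at Chebyshev cell
// distance k can only contain points at distance >= (k - 1) * cell, so
// the scan stops as soon as that bound strictly exceeds the current best
// (which also protects the lowest-index tie-break: any later candidate
// would be strictly farther).
// [[Rcpp::export(name = ".nnd_grid")]]
List nnd_grid(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 2) stop("need at least 2 points");

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  double wx = std::max(xmax - xmin, 1e-12);
  double wy = std::max(ymax - ymin, 1e-12);
  // aim for ~1 point per cell; the second term keeps the grid coarse for
  // degenerate (near-collinear) bounding boxes, and the loop caps the
  // total cell count so memory stays O(n)
  double cell = std::max(std::sqrt(wx * wy / n),
                         std::max(wx, wy) / (8.0 * std::sqrt((double)n)));
  if (cell <= 0) cell = 1e-12;
  while ((wx / cell) * (wy / cell) > 4.0 * n + 64.0) cell *= 2.0;
  int ncx = std::max(1, (int)std::ceil(wx / cell));
  int ncy = std::max(1, (int)std::ceil(wy / cell));

  std::vector<std::vector<int> > buckets((size_t)ncx * ncy);
  std::vector<int> cxs(n), cys(n);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(ncx - 1, (int)((x[i] - xmin) / cell));
    int cy = std::min(ncy - 1, (int)((y[i] - ymin) / cell));
    cxs[i] = cx; cys[i] = cy;
    buckets[(size_t)cy * ncx + cx].push_back(i);
  }

  NumericVector nnd(n);
  IntegerVector nb(n);
  int maxring = std::max(ncx, ncy);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bestj = -1;
    for (int k = 0; k <= maxring; ++k) {
      if (bestj >= 0 && (double)(k - 1) * cell > best) break;
      int cx0 = cxs[i] - k, cx1 = cxs[i] + k;
      int cy0 = cys[i] - k, cy1 = cys[i] + k;
      for (int cy = cy0; cy <= cy1; ++cy) {
        if (cy < 0 || cy >= ncy) continue;
        for (int cx = cx0; cx <= cx1; ++cx) {
          if (cx < 0 || cx >= ncx) continue;
          // ring only: skip interior cells already visited
          if (k > 0 && cx != cx0 && cx != cx1 && cy != cy0 && cy != cy1)
            continue;
          const std::vector<int>& b = buckets[(size_t)cy * ncx + cx];
          for (size_t m = 0; m < b.size(); ++m) {
            int j = b[m];
            if (j == i) continue;
            double dx = x[j] - x[i], dy = y[j] - y[i];
            double d = std::sqrt(dx * dx + dy * dy);
            if (d < best || (d == best && j < bestj)) {
              best = d; bestj = j;
            }
          }
        }
      }
    }
    nnd[i] = best;
    nb[i] = bestj + 1;  // 1-based
  }
  return List::create(_["nnd"] = nnd, _["neighbor"] = nb);
}
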