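#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Count, for every pixel, how many inter-point segments of a polyline cross
// it. Coordinates are continuous raster coordinates: x in [0, W] maps to
// columns, y in [0, H] to rows; pixel (r, c) covers [r, r+1) x [c, c+1).
// Grid traversal is the standard DDA over pixel boundaries; every pixel a
// segment passes through is incremented once per segment.
// [[Rcpp::export]]
IntegerMatrix raster_segments_cpp(NumericMatrix xy, int height, int width) {
  IntegerMatrix grid(height, width);
  const int n = xy.nrow();
  if (n == 0) return grid;

  auto clampi = [](int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
  };

  if (n == 1) {
    int cx = clampi((int)std::floor(xy(0, 0)), 0, width - 1);
    int cy = clampi((int)std::floor(xy(0, 1)), 0, height - 1);
    grid(cy, cx) += 1;
    return grid;
  }

  for (int s = 0; s + 1 < n; ++s) {
    double x0 = xy(s, 0), y0 = xy(s, 1);
    double x1 = xy(s + 1, 0), y1 = xy(s + 1, 1);
    int cx = clampi((int)std::floor(x0), 0, width - 1);
    int cy = clampi((int)std::floor(y0), 0, height - 1);
    int ex = clampi((int)std::floor(x1), 0, width - 1);
    int ey = clampi((int)std::floor(y1), 0, height - 1);
    double dx = x1 - x0, dy = y1 - y0;
    int stepX = dx > 0 ? 1 : -1;
    int stepY = dy > 0 ? 1 : -1;
    // next grid boundary to cross in each direction
    int nbx = stepX > 0 ? cx + 1 : cx;
    int nby = stepY > 0 ? cy + 1 : cy;
    // crossing parameters are recomputed from the endpoints each step (not
    // accumulated), so corner ties are detected exactly
    auto tX = [&]() { return dx != 0 ? (nbx - x0) / dx : R_PosInf; };
    auto tY = [&]() { return dy != 0 ? (nby - y0) / dy : R_PosInf; };

    grid(cy, cx) += 1;
    const double corner_tol = 1e-9;  // passes this close to a pixel corner
                                     // count as corner crossings
    int guard = 2 * (width + height) + 4;
    while ((cx != ex || cy != ey) && guard-- > 0) {
      double tx = tX(), ty = tY();
      if (tx < ty - corner_tol) {
        cx += stepX;
        nbx += stepX;
      } else if (ty < tx - corner_tol) {
        cy += stepY;
        nby += stepY;
      } else {
        // corner crossing: the segment enters the diagonal neighbor; the
        // two corner-adjacent pixels are touched only at a sliver and are
        // not counted as crossed
        cx += stepX;
        cy += stepY;
        nbx += stepX;
        nby += stepY;
      }
      if (cx < 0 || cx >= width || cy < 0 || cy >= height) break;
      grid(cy, cx) += 1;
    }
  }
  return grid;
}
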