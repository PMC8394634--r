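#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Siddon-style exact ray/pixel intersection lengths for a parallel-beam
// geometry over a square image of n x n unit pixels centred on the rotation
// isocenter.
//
// Conventions (fixed; the rasterizer and reconstructions rely on them):
//  * world coordinates: x to the right, y upwards, origin at the isocenter;
//    the image occupies [-n/2, n/2]^2;
//  * image matrix element (row r, col c), 1-based, has its pixel centre at
//    x = c - 0.5 - n/2, y = n/2 - (r - 0.5)  (row 1 is the top of the image);
//  * pixels are flattened column-major: linear index = (c-1)*n + r;
//  * view angle theta (degrees): detector axis u = (cos t, sin t), ray
//    direction v = (-sin t, cos t); the ray for detector coordinate tdet is
//    { tdet*u + s*v : s real };
//  * rays are indexed view-major: ray i = view*n_bins + bin (0-based here,
//    1-based triplets are returned for Matrix::sparseMatrix).
//
// Each ray is traced by collecting the parameters of all axis-line crossings
// inside the image square, sorting them, and attributing each inter-crossing
// segment to the pixel containing its midpoint. Robust to rays that touch
// pixel corners or run along grid lines (zero-length segments are dropped).

// [[Rcpp::export]]
List siddon_trace(int image_size, NumericVector angles_deg,
                  NumericVector det_coords, double pixel_size) {
  const int n = image_size;
  const double half = n / 2.0;
  const int n_views = angles_deg.size();
  const int n_bins = det_coords.size();

  std::vector<int> ri, ci;       // triplet row (ray) / col (pixel), 1-based
  std::vector<double> wi;        // intersection length * pixel_size
  ri.reserve(static_cast<size_t>(n_views) * n_bins * 8);
  ci.reserve(ri.capacity());
  wi.reserve(ri.capacity());

  std::vector<double> cross;
  cross.reserve(2 * n + 4);

  for (int v = 0; v < n_views; ++v) {
    const double th = angles_deg[v] * M_PI / 180.0;
    const double ux = std::cos(th), uy = std::sin(th);
    const double dx = -uy, dy = ux;  // unit ray direction

    for (int b = 0; b < n_bins; ++b) {
      const double t = det_coords[b];
      // ray origin in grid frame: gx in [0,n] left->right, gy in [0,n]
      // top->bottom (gy = half - y)
      const double ox = t * ux + half;
      const double oy = half - t * uy;
      const double gx = dx, gy = -dy;  // direction in grid frame (unit)

      // clip s to the image square [0,n]^2 (slab method)
      double smin = -1e30, smax = 1e30;
      bool miss = false;
      const double od[2] = {ox, oy}, dd[2] = {gx, gy};
      for (int ax = 0; ax < 2; ++ax) {
        if (std::fabs(dd[ax]) < 1e-14) {
          if (od[ax] <= 0.0 || od[ax] >= n) { miss = true; break; }
        } else {
          double s0 = (0.0 - od[ax]) / dd[ax];
          double s1 = (n - od[ax]) / dd[ax];
          if (s0 > s1) std::swap(s0, s1);
          smin = std::max(smin, s0);
          smax = std::min(smax, s1);
        }
      }
      if (miss || smax - smin < 1e-12) continue;  // zero row: ray misses

      cross.clear();
      cross.push_back(smin);
      cross.push_back(smax);
      if (std::fabs(gx) > 1e-14) {
        const double xa = ox + gx * smin, xb = ox + gx * smax;
        const int k0 = static_cast<int>(std::ceil(std::min(xa, xb) - 1e-12));
        const int k1 = static_cast<int>(std::floor(std::max(xa, xb) + 1e-12));
        for (int k = std::max(k0, 0); k <= std::min(k1, n); ++k) {
          const double s = (k - ox) / gx;
          if (s > smin + 1e-12 && s < smax - 1e-12) cross.push_back(s);
        }
      }
      if (std::fabs(gy) > 1e-14) {
        const double ya = oy + gy * smin, yb = oy + gy * smax;
        const int k0 = static_cast<int>(std::ceil(std::min(ya, yb) - 1e-12));
        const int k1 = static_cast<int>(std::floor(std::max(ya, yb) + 1e-12));
        for (int k = std::max(k0, 0); k <= std::min(k1, n); ++k) {
          const double s = (k - oy) / gy;
          if (s > smin + 1e-12 && s < smax - 1e-12) cross.push_back(s);
        }
      }
      std::sort(cross.begin(), cross.end());

      const int ray = v * n_bins + b + 1;  // 1-based
      for (size_t k = 0; k + 1 < cross.size(); ++k) {
        const double len = cross[k + 1] - cross[k];
        if (len < 1e-12) continue;
        const double sm = 0.5 * (cross[k] + cross[k + 1]);
        int ix = static_cast<int>(std::floor(ox + gx * sm));
        int iy = static_cast<int>(std::floor(oy + gy * sm));
        if (ix < 0) ix = 0; else if (ix >= n) ix = n - 1;
        if (iy < 0) iy = 0; else if (iy >= n) iy = n - 1;
        ri.push_back(ray);
        ci.push_back(ix * n + iy + 1);  // column-major linear pixel index
        wi.push_back(len * pixel_size);
      }
    }
  }

  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci),
                      _["x"] = wrap(wi));
}
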