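// Overdamped Langevin walker with metadynamics hill deposition on a 2D
// angular collective-variable space. The accumulated bias gradient is kept
// on a grid (each deposition adds a truncated Gaussian patch), so the cost
// per step is O(1) in the number of hills. Uses R's RNG (norm_rand), so
// set.seed() on the R side gives bit-reproducible trajectories.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap180(double x) {
  double w = x - 360.0 * std::floor((x + 180.0) / 360.0);
  if (w == -180.0) w = 180.0;
  return w;
}

// potential codes: 0 flat, 1 harmonic, 2 doublewell
static void grad_potential(int type, const NumericVector& p,
                           double x, double y, double& gx, double& gy) {
  switch (type) {
  case 0:
    gx = 0.0; gy = 0.0; break;
  case 1: {
    // p = cx, cy, k
    double dx = wrap180(x - p[0]), dy = wrap180(y - p[1]);
    gx = p[2] * dx; gy = p[2] * dy; break;
  }
  case 2: {
    // p = x1, x2, yc, sigma_w, B, dF, ky
    double u1 = wrap180(x - p[0]), u2 = wrap180(x - p[1]);
    double dy = wrap180(y - p[2]);
    double s2 = p[3] * p[3];
    double g1 = std::exp(-u1 * u1 / (2.0 * s2));
    double g2 = std::exp(-u2 * u2 / (2.0 * s2));
    gx = p[4] * g1 * u1 / s2 + (p[4] - p[5]) * g2 * u2 / s2;
    gy = p[6] * dy;
    break;
  }
  default:
    stop("unknown potential code");
  }
}

struct BiasGrid {
  int nx, ny;
  double x0, y0, dx, dy;
  bool periodic;
  std::vector<double> gvx, gvy; // dV/dx, dV/dy at grid nodes

  BiasGrid(int nx_, int ny_, double x0_, double y0_, double dx_, double dy_,
           bool per) : nx(nx_), ny(ny_), x0(x0_), y0(y0_), dx(dx_), dy(dy_),
                       periodic(per), gvx(nx_ * ny_, 0.0), gvy(nx_ * ny_, 0.0) {}

  inline int wrap_ix(int i) const {
    if (periodic) { i %= nx; if (i < 0) i += nx; return i; }
    return i < 0 ? 0 : (i >= nx ? nx - 1 : i);
  }
  inline int wrap_iy(int j) const {
    if (periodic) { j %= ny; if (j < 0) j += ny; return j; }
    return j < 0 ? 0 : (j >= ny ? ny - 1 : j);
  }

  // With reflecting walls the hill mass falling outside the window must be
  // mirrored back in, otherwise boundary cells are systematically
  // under-biased and the walker piles up against the walls.
  void deposit(double hx, double hy, double h, double sigma) {
    if (!periodic) {
      double xlo = x0, xhi = x0 + nx * dx, ylo = y0, yhi = y0 + ny * dy;
      double xs[3] = {hx, 2 * xlo - hx, 2 * xhi - hx};
      double ys[3] = {hy, 2 * ylo - hy, 2 * yhi - hy};
      for (int a = 0; a < 3; ++a) {
        if (xs[a] < xlo - 4.5 * sigma || xs[a] > xhi + 4.5 * sigma) continue;
        for (int b = 0; b < 3; ++b) {
          if (ys[b] < ylo - 4.5 * sigma || ys[b] > yhi + 4.5 * sigma) continue;
          deposit_one(xs[a], ys[b], h, sigma);
        }
      }
    } else {
      deposit_one(hx, hy, h, sigma);
    }
  }

  void deposit_one(double hx, double hy, double h, double sigma) {
    double s2 = sigma * sigma;
    int rx = (int)std::ceil(4.5 * sigma / dx);
    int ry = (int)std::ceil(4.5 * sigma / dy);
    int ix0 = (int)std::floor((hx - x0) / dx);
    int iy0 = (int)std::floor((hy - y0) / dy);
    for (int di = -rx; di <= rx + 1; ++di) {
      int iw = ix0 + di;
      if (!periodic && (iw < 0 || iw >= nx)) continue;
      int i = wrap_ix(iw);
      double px = x0 + iw * dx;
      double ddx = periodic ? wrap180(px - hx) : (px - hx);
      double ex = std::exp(-ddx * ddx / (2.0 * s2));
      if (ex < 1e-12) continue;
      for (int dj = -ry; dj <= ry + 1; ++dj) {
        int jw = iy0 + dj;
        if (!periodic && (jw < 0 || jw >= ny)) continue;
        int j = wrap_iy(jw);
        double py = y0 + jw * dy;
        double ddy = periodic ? wrap180(py - hy) : (py - hy);
        double e = h * ex * std::exp(-ddy * ddy / (2.0 * s2));
        gvx[j * nx + i] += -e * ddx / s2;
        gvy[j * nx + i] += -e * ddy / s2;
      }
    }
  }

  void interp(double x, double y, double& bx, double& by) const {
    double fx = (x - x0) / dx, fy = (y - y0) / dy;
    int i = (int)std::floor(fx), j = (int)std::floor(fy);
    double tx = fx - i, ty = fy - j;
    int i0 = wrap_ix(i), i1 = wrap_ix(i + 1);
    int j0 = wrap_iy(j), j1 = wrap_iy(j + 1);
    double w00 = (1 - tx) * (1 - ty), w10 = tx * (1 - ty),
           w01 = (1 - tx) * ty, w11 = tx * ty;
    bx = w00 * gvx[j0 * nx + i0] + w10 * gvx[j0 * nx + i1] +
         w01 * gvx[j1 * nx + i0] + w11 * gvx[j1 * nx + i1];
    by = w00 * gvy[j0 * nx + i0] + w10 * gvy[j0 * nx + i1] +
         w01 * gvy[j1 * nx + i0] + w11 * gvy[j1 * nx + i1];
  }
};

// [[Rcpp::export(name = ".metadyn_walk_cpp")]]
List metadyn_walk_cpp(int pot_type, NumericVector pot_params,
                      double x0, double y0,
                      int n_steps, int deposition_interval,
                      double hill_height, double hill_sigma,
                      double kT, double mobility,
                      NumericVector bounds,   // length 0 (periodic) or 4: x_lo, x_hi, y_lo, y_hi
                      double grid_spacing,
                      int sample_interval) {
  bool bounded = bounds.size() == 4;
  double xlo = bounded ? bounds[0] : -180.0, xhi = bounded ? bounds[1] : 180.0;
  double ylo = bounded ? bounds[2] : -180.0, yhi = bounded ? bounds[3] : 180.0;
  int nx = std::max(8, (int)std::round((xhi - xlo) / grid_spacing));
  int ny = std::max(8, (int)std::round((yhi - ylo) / grid_spacing));
  BiasGrid grid(nx, ny, xlo, ylo, (xhi - xlo) / nx, (yhi - ylo) / ny, !bounded);

  int n_hills = (deposition_interval > 0 && hill_height > 0)
                  ? n_steps / deposition_interval : 0;
  NumericMatrix hills(n_hills, 3);
  int n_samp = sample_interval > 0 ? n_steps / sample_interval : 0;
  NumericMatrix samples(n_samp, 2);

  double x = x0, y = y0;
  double noise_sd = std::sqrt(2.0 * kT * mobility);
  int hi = 0, si = 0;
  RNGScope scope;

  for (int step = 1; step <= n_steps; ++step) {
    double gx, gy, bx = 0.0, by = 0.0;
    grad_potential(pot_type, pot_params, x, y, gx, gy);
    grid.interp(x, y, bx, by);
    double sx = -mobility * (gx + bx) + noise_sd * norm_rand();
    double sy = -mobility * (gy + by) + noise_sd * norm_rand();
    if (std::fabs(sx) > 90.0 || std::fabs(sy) > 90.0 ||
        !std::isfinite(sx) || !std::isfinite(sy)) {
      stop("divergent step (|ds| > 90 deg) at step %d: reduce dt or friction", step);
    }
    x += sx; y += sy;
    if (bounded) {
      while (x < xlo || x > xhi) x = x < xlo ? 2 * xlo - x : 2 * xhi - x;
      while (y < ylo || y > yhi) y = y < ylo ? 2 * ylo - y : 2 * yhi - y;
    } else {
      x = wrap180(x); y = wrap180(y);
    }
    if (deposition_interval > 0 && hill_height > 0 &&
        step % deposition_interval == 0 && hi < n_hills) {
      hills(hi, 0) = step; hills(hi, 1) = x; hills(hi, 2) = y;
      ++hi;
      grid.deposit(x, y, hill_height, hill_sigma);
    }
    if (sample_interval > 0 && step % sample_interval == 0 && si < n_samp) {
      samples(si, 0) = x; samples(si, 1) = y;
      ++si;
    }
  }
  return List::create(_["hills"] = hills, _["samples"] = samples);
}
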