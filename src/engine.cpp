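#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Nearest-neighbour RED sample; returns 0 (vacuum/air) outside the grid.
static inline double sample_red(const double* red, const int* n,
                                const double* org, const double* sp,
                                double x, double y, double z, bool& inside) {
  int i = (int)std::lround((x - org[0]) / sp[0]);
  int j = (int)std::lround((y - org[1]) / sp[1]);
  int k = (int)std::lround((z - org[2]) / sp[2]);
  if (i < 0 || i >= n[0] || j < 0 || j >= n[1] || k < 0 || k >= n[2]) {
    inside = false;
    return 0.0;
  }
  inside = true;
  return red[i + (size_t)n[0] * (j + (size_t)n[1] * k)];
}

static inline double edge_profile(double u, double hw, double sigma) {
  const double s = sigma * M_SQRT2;
  return 0.5 * (std::erf((hw - u) / s) + std::erf((hw + u) / s));
}

// Parallel-beam toy dose engine with exponential attenuation along the
// radiological path and an interface (ERE-like) perturbation term.
// Beams lie in the axial plane; angles give the direction from the
// isocentre toward the source. Output is an unnormalised dose array on
// the RED grid.
// [[Rcpp::export]]
NumericVector engine_dose_cpp(NumericVector red, IntegerVector shape,
                              NumericVector spacing, NumericVector origin,
                              NumericVector beam_angles_deg, NumericVector iso,
                              double halfwidth, double halfheight,
                              double mu_mm, double sigma_mm,
                              double ere_gain, double ere_range_mm,
                              double red_sat, double step_mm,
                              double red_lo, double scan_mm) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const double* rp = red.begin();
  const int n[3] = {nx, ny, nz};
  const double org[3] = {origin[0], origin[1], origin[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  NumericVector dose((size_t)nx * ny * nz);
  const double rmin_decay = 0.05;  // caps the in-cavity rebuild length

  for (int b = 0; b < beam_angles_deg.size(); ++b) {
    const double a = beam_angles_deg[b] * M_PI / 180.0;
    const double sx = std::cos(a), sy = std::sin(a);  // toward source
    const double ux = -sy, uy = sx;                    // lateral in-plane
    for (int k = 0; k < nz; ++k) {
      const double pz = org[2] + k * sp[2];
      const double v = pz - iso[2];
      const double pv = edge_profile(v, halfheight, sigma_mm);
      if (pv < 1e-4) continue;
      for (int j = 0; j < ny; ++j) {
        const double py = org[1] + j * sp[1];
        for (int i = 0; i < nx; ++i) {
          const double px = org[0] + i * sp[0];
          const double wx = px - iso[0], wy = py - iso[1];
          const double u = wx * ux + wy * uy;
          const double pu = edge_profile(u, halfwidth, sigma_mm);
          const double prof = pu * pv;
          if (prof < 1e-4) continue;

          // radiological path from the voxel back toward the source
          double radlen = 0.0;
          bool inside = true;
          for (double t = 0.5 * step_mm; ; t += step_mm) {
            double r = sample_red(rp, n, org, sp,
                                  px + sx * t, py + sy * t, pz, inside);
            if (!inside) break;
            radlen += r * step_mm;
          }

          // interface perturbation
          double factor = 1.0;
          if (ere_gain > 0.0) {
            bool ok = true;
            double rv = sample_red(rp, n, org, sp, px, py, pz, ok);
            if (rv < red_lo) {
              // inside a cavity: find upstream solid edge
              for (double t = step_mm; t <= scan_mm; t += step_mm) {
                double r = sample_red(rp, n, org, sp,
                                      px + sx * t, py + sy * t, pz, ok);
                if (!ok) break;  // left the grid: entrance region, no ERE
                if (r >= red_lo) {
                  double amp = 1.0 - rv / red_sat;
                  if (amp > 0.0) {
                    double lam = ere_range_mm / std::max(rv, rmin_decay);
                    factor = 1.0 - ere_gain * amp * std::exp(-t / lam);
                  }
                  break;
                }
              }
            } else {
              // solid: boost on the proximal side of a downstream cavity
              for (double t = step_mm; t <= scan_mm; t += step_mm) {
                double r = sample_red(rp, n, org, sp,
                                      px - sx * t, py - sy * t, pz, ok);
                if (!ok) break;
                if (r < red_lo) {
                  double amp = 1.0 - r / red_sat;
                  if (amp > 0.0)
                    factor = 1.0 + 0.5 * ere_gain * amp *
                             std::exp(-t / ere_range_mm);
                  break;
                }
              }
            }
            if (factor < 0.0) factor = 0.0;
          }

          dose[i + (size_t)nx * (j + (size_t)ny * k)] +=
            prof * std::exp(-mu_mm * radlen) * factor;
        }
      }
    }
  }
  return dose;
}

// Exhaustive 2-D gamma reference: dense offset grid (step, radius given in
// mm), offsets visited in order of increasing distance with the standard
// early-exit bound gamma^2 >= (r/dta)^2, which cannot change the minimum.
// Returns the gamma map with NA below the dose threshold.
// [[Rcpp::export]]
NumericMatrix gamma_brute_cpp(NumericMatrix ref, NumericMatrix ev,
                              double dx, double dy, double dd_gy,
                              double thr_gy, double dta,
                              double step, double radius) {
  const int nx = ref.nrow(), ny = ref.ncol();
  const int ns = (int)std::floor(radius / step);
  std::vector<std::pair<double, std::pair<double,double> > > offs;
  offs.reserve((size_t)(2 * ns + 1) * (2 * ns + 1));
  for (int oy = -ns; oy <= ns; ++oy)
    for (int ox = -ns; ox <= ns; ++ox) {
      double rx = ox * step, ry = oy * step;
      double r2 = (rx * rx + ry * ry) / (dta * dta);
      if (r2 <= (radius / dta) * (radius / dta) + 1e-12)
        offs.push_back(std::make_pair(r2, std::make_pair(rx, ry)));
    }
  std::sort(offs.begin(), offs.end());

  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (ref(i, j) < thr_gy) { out(i, j) = NA_REAL; continue; }
      const double px = i * dx, py = j * dy, rd = ref(i, j);
      double best = R_PosInf;
      for (size_t m = 0; m < offs.size(); ++m) {
        const double r2 = offs[m].first;
        if (r2 >= best) break;
        const double qx = px + offs[m].second.first;
        const double qy = py + offs[m].second.second;
        const double gx = qx / dx, gy = qy / dy;
        if (gx < 0 || gx > nx - 1 || gy < 0 || gy > ny - 1) continue;
        int x0 = (int)std::floor(gx); if (x0 > nx - 2) x0 = nx - 2;
        int y0 = (int)std::floor(gy); if (y0 > ny - 2) y0 = ny - 2;
        if (nx == 1) x0 = 0;
        if (ny == 1) y0 = 0;
        const double fx = gx - x0, fy = gy - y0;
        double val = ev(x0, y0) * (1 - fx) * (1 - fy);
        if (nx > 1) val += ev(x0 + 1, y0) * fx * (1 - fy);
        if (ny > 1) val += ev(x0, y0 + 1) * (1 - fx) * fy;
        if (nx > 1 && ny > 1) val += ev(x0 + 1, y0 + 1) * fx * fy;
        const double dd = (val - rd) / dd_gy;
        const double g2 = dd * dd + r2;
        if (g2 < best) best = g2;
      }
      out(i, j) = std::sqrt(best);
    }
  return out;
}
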