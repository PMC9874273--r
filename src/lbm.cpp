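// D2Q9 lattice-Boltzmann (BGK) solver for unsteady 2-D flow past a
// circular cylinder: equilibrium inflow, zero-gradient outflow, free-slip
// (specular) lateral walls, full-way bounce-back cylinder. Deterministic:
// no randomness anywhere. All quantities are in lattice units; the R side
// rescales to physical units via the free-stream speed and the cylinder
// diameter.
//
// Layout: f[i][x * ny + y], y contiguous. Streaming is a constant-offset
// shift per direction, done as bulk column copies; the free-slip walls and
// the open x boundaries are patched afterwards.
#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>
using namespace Rcpp;

static const int ex[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
static const int ey[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
static const double w[9] = {4.0 / 9,  1.0 / 9,  1.0 / 9, 1.0 / 9, 1.0 / 9,
                            1.0 / 36, 1.0 / 36, 1.0 / 36, 1.0 / 36};
static const int opp[9] = {0, 3, 4, 1, 2, 7, 8, 5, 6};
// direction after specular reflection at a horizontal wall (ey -> -ey)
static const int mir[9] = {0, 1, 4, 3, 2, 8, 7, 6, 5};

static inline double feq(int i, double rho, double ux, double uy) {
  double eu = ex[i] * ux + ey[i] * uy;
  double u2 = ux * ux + uy * uy;
  return w[i] * rho * (1.0 + 3.0 * eu + 4.5 * eu * eu - 1.5 * u2);
}

// [[Rcpp::export]]
List lbm_run(int nx, int ny, double cx, double cy, double radius,
             double u_in, double tau, int n_steps, int sample_every,
             int field_every, NumericMatrix probe_xy, int probe_every,
             double perturb) {
  const int nc = nx * ny;
  std::vector<std::vector<double>> f(9, std::vector<double>(nc)),
      ftmp(9, std::vector<double>(nc));
  std::vector<unsigned char> solid(nc, 0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double dx = x - cx, dy = y - cy;
      if (radius > 0 && dx * dx + dy * dy <= radius * radius)
        solid[x * ny + y] = 1;
    }

  // initial state: uniform inflow plus a small deterministic cross-stream
  // perturbation to break symmetry and trigger shedding
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int c = x * ny + y;
      double uy0 = perturb * u_in * std::sin(2.0 * M_PI * x / nx);
      for (int i = 0; i < 9; ++i)
        f[i][c] = feq(i, 1.0, solid[c] ? 0.0 : u_in, solid[c] ? 0.0 : uy0);
    }

  const int n_samples = n_steps / sample_every;
  const int n_snaps = n_steps / field_every;
  const int n_probes = probe_xy.nrow();
  const int n_probe_steps = n_steps / probe_every;
  NumericVector speed_out((R_xlen_t)n_samples * nc);
  NumericVector u_snap((R_xlen_t)n_snaps * nc), v_snap((R_xlen_t)n_snaps * nc),
      r_snap((R_xlen_t)n_snaps * nc);
  NumericVector probe_u((R_xlen_t)n_probe_steps * n_probes),
      probe_v((R_xlen_t)n_probe_steps * n_probes),
      probe_r((R_xlen_t)n_probe_steps * n_probes);
  IntegerVector sample_steps(n_samples), snap_steps(n_snaps),
      probe_steps(n_probe_steps);

  std::vector<double> rho(nc, 1.0), ux(nc, u_in), uy(nc, 0.0);
  const double omega = 1.0 / tau;

  for (int step = 1; step <= n_steps; ++step) {
    const bool record = (step % probe_every == 0) ||
                        (step % sample_every == 0) ||
                        (step % field_every == 0) || (step % 500 == 0);

    // collision (fluid) / bounce-back swap (solid), purely local
    for (int c = 0; c < nc; ++c) {
      if (solid[c]) {
        double tmp[9];
        for (int i = 0; i < 9; ++i) tmp[i] = f[opp[i]][c];
        for (int i = 0; i < 9; ++i) f[i][c] = tmp[i];
        continue;
      }
      double f0 = f[0][c], f1 = f[1][c], f2 = f[2][c], f3 = f[3][c],
             f4 = f[4][c], f5 = f[5][c], f6 = f[6][c], f7 = f[7][c],
             f8 = f[8][c];
      double r = f0 + f1 + f2 + f3 + f4 + f5 + f6 + f7 + f8;
      double vx = (f1 - f3 + f5 - f6 - f7 + f8) / r;
      double vy = (f2 - f4 + f5 + f6 - f7 - f8) / r;
      if (record) { rho[c] = r; ux[c] = vx; uy[c] = vy; }
      double u2 = vx * vx + vy * vy;
      double c0 = 1.0 - 1.5 * u2;
      // equilibria written out for speed
      f[0][c] = f0 + omega * (w[0] * r * c0 - f0);
      double e;
      e = vx;  f[1][c] = f1 + omega * (w[1] * r * (c0 + 3 * e + 4.5 * e * e) - f1);
      e = vy;  f[2][c] = f2 + omega * (w[2] * r * (c0 + 3 * e + 4.5 * e * e) - f2);
      e = -vx; f[3][c] = f3 + omega * (w[3] * r * (c0 + 3 * e + 4.5 * e * e) - f3);
      e = -vy; f[4][c] = f4 + omega * (w[4] * r * (c0 + 3 * e + 4.5 * e * e) - f4);
      e = vx + vy;  f[5][c] = f5 + omega * (w[5] * r * (c0 + 3 * e + 4.5 * e * e) - f5);
      e = -vx + vy; f[6][c] = f6 + omega * (w[6] * r * (c0 + 3 * e + 4.5 * e * e) - f6);
      e = -vx - vy; f[7][c] = f7 + omega * (w[7] * r * (c0 + 3 * e + 4.5 * e * e) - f7);
      e = vx - vy;  f[8][c] = f8 + omega * (w[8] * r * (c0 + 3 * e + 4.5 * e * e) - f8);
    }

    // streaming: constant-offset bulk copy per direction
    for (int i = 0; i < 9; ++i) {
      const int exi = ex[i], eyi = ey[i];
      const int x_lo = exi > 0 ? exi : 0, x_hi = nx - 1 + (exi < 0 ? exi : 0);
      const int y_lo = eyi > 0 ? eyi : 0, y_hi = ny - 1 + (eyi < 0 ? eyi : 0);
      const int len = y_hi - y_lo + 1;
      const double *src0 = f[i].data();
      double *dst0 = ftmp[i].data();
      for (int x = x_lo; x <= x_hi; ++x) {
        std::memcpy(dst0 + x * ny + y_lo,
                    src0 + (x - exi) * ny + (y_lo - eyi),
                    sizeof(double) * len);
      }
    }
    // free-slip walls: populations leaving through y = 0 / y = ny-1
    // re-enter the same row with the vertical component mirrored
    for (int i : {4, 7, 8}) { // ey = -1, reflect at bottom wall
      int j = mir[i];
      for (int x = std::max(0, ex[i]); x <= nx - 1 + std::min(0, ex[i]); ++x)
        ftmp[j][x * ny + 0] = f[i][(x - ex[i]) * ny + 0];
    }
    for (int i : {2, 5, 6}) { // ey = +1, reflect at top wall
      int j = mir[i];
      for (int x = std::max(0, ex[i]); x <= nx - 1 + std::min(0, ex[i]); ++x)
        ftmp[j][x * ny + (ny - 1)] = f[i][(x - ex[i]) * ny + (ny - 1)];
    }
    for (int i = 0; i < 9; ++i) f[i].swap(ftmp[i]);

    // inflow: equilibrium at (1, u_in); outflow: zero-gradient copy
    for (int i = 0; i < 9; ++i) {
      const double fin = feq(i, 1.0, u_in, 0.0);
      double *fi = f[i].data();
      for (int y = 0; y < ny; ++y) fi[y] = fin;
      std::memcpy(fi + (nx - 1) * ny, fi + (nx - 2) * ny,
                  sizeof(double) * ny);
    }

    if (!record) continue;
    if (step % probe_every == 0) {
      int pi = step / probe_every - 1;
      probe_steps[pi] = step;
      for (int p = 0; p < n_probes; ++p) {
        double px = probe_xy(p, 0), py = probe_xy(p, 1);
        int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
        if (x0 < 0) x0 = 0; if (x0 > nx - 2) x0 = nx - 2;
        if (y0 < 0) y0 = 0; if (y0 > ny - 2) y0 = ny - 2;
        double fx = px - x0, fy = py - y0;
        double uu = 0.0, vv = 0.0, rr = 0.0;
        for (int a = 0; a <= 1; ++a)
          for (int b = 0; b <= 1; ++b) {
            double wgt = (a ? fx : 1 - fx) * (b ? fy : 1 - fy);
            int c = (x0 + a) * ny + (y0 + b);
            uu += wgt * ux[c]; vv += wgt * uy[c]; rr += wgt * rho[c];
          }
        probe_u[(R_xlen_t)pi * n_probes + p] = uu;
        probe_v[(R_xlen_t)pi * n_probes + p] = vv;
        probe_r[(R_xlen_t)pi * n_probes + p] = rr;
      }
    }
    if (step % sample_every == 0) {
      int si = step / sample_every - 1;
      sample_steps[si] = step;
      for (int c = 0; c < nc; ++c)
        speed_out[(R_xlen_t)si * nc + c] =
            solid[c] ? NA_REAL : std::sqrt(ux[c] * ux[c] + uy[c] * uy[c]);
    }
    if (step % field_every == 0) {
      int fi2 = step / field_every - 1;
      snap_steps[fi2] = step;
      for (int c = 0; c < nc; ++c) {
        u_snap[(R_xlen_t)fi2 * nc + c] = solid[c] ? NA_REAL : ux[c];
        v_snap[(R_xlen_t)fi2 * nc + c] = solid[c] ? NA_REAL : uy[c];
        r_snap[(R_xlen_t)fi2 * nc + c] = solid[c] ? NA_REAL : rho[c];
      }
    }
    // stability guard: local speed must stay well below lattice sound speed
    if (step % 500 == 0) {
      for (int c = 0; c < nc; ++c)
        if (!std::isfinite(rho[c]) ||
            ux[c] * ux[c] + uy[c] * uy[c] > 0.49 * 0.49)
          stop("numerical instability: local Mach limit exceeded (CFL "
               "constraint violated) at step %d", step);
    }
  }

  IntegerVector solid_out(nc);
  for (int c = 0; c < nc; ++c) solid_out[c] = solid[c];
  return List::create(
      _["speed"] = speed_out, _["sample_steps"] = sample_steps,
      _["u_snap"] = u_snap, _["v_snap"] = v_snap, _["rho_snap"] = r_snap,
      _["snap_steps"] = snap_steps, _["probe_u"] = probe_u,
      _["probe_v"] = probe_v, _["probe_rho"] = probe_r,
      _["probe_steps"] = probe_steps, _["solid"] = solid_out);
}
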