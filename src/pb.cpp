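// Finite-difference linearized Poisson(-Boltzmann) solver on a uniform cubic
// grid. Dielectric assigned on grid faces (eps_in inside any atom sphere,
// eps_out elsewhere), charges spread trilinearly to nodes, Dirichlet
// boundaries from the analytic screened-Coulomb potential, SOR iteration.
// The reaction-field (polar solvation) energy is the difference between the
// heterogeneous solve and a homogeneous eps_in solve on the same grid, which
// cancels the discrete self-energy.
// Potential unit: kJ/mol/e; Poisson equation div(eps grad phi) = -4 pi f rho
// with f = 138.935458 so that a charge q in uniform eps gives f q / (eps r).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double FPB = 138.935458;
static const double FOUR_PI = 12.566370614359172;

struct Grid {
  int nx, ny, nz;
  double h, ox, oy, oz;
  inline size_t idx(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  }
};

// SOR solve of div(eps grad phi) = -4 pi f rho with Dirichlet boundary
// already stored in phi at the outermost layer. Returns iterations used,
// or -1 on non-convergence.
static int sor_solve(const Grid &g, const std::vector<double> &ex,
                     const std::vector<double> &ey, const std::vector<double> &ez,
                     const std::vector<double> &src,
                     const std::vector<double> &diag_extra,
                     std::vector<double> &phi, int maxiter, double tol) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  double omega = 2.0 / (1.0 + std::sin(M_PI / std::max(nx, std::max(ny, nz))));
  double scale = 0.0;
  for (size_t t = 0; t < phi.size(); ++t)
    scale = std::max(scale, std::fabs(phi[t]));
  for (size_t t = 0; t < src.size(); ++t)
    scale = std::max(scale, std::fabs(src[t]));
  if (scale == 0.0) return 0;  // all-zero problem
  const double thresh = tol * scale;
  auto fx = [&](int i, int j, int k) {
    return ex[(size_t)i + (size_t)(nx - 1) * ((size_t)j + (size_t)ny * k)];
  };
  auto fy = [&](int i, int j, int k) {
    return ey[(size_t)i + (size_t)nx * ((size_t)j + (size_t)(ny - 1) * k)];
  };
  auto fz = [&](int i, int j, int k) {
    return ez[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  };
  for (int it = 1; it <= maxiter; ++it) {
    double maxdiff = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          size_t c = g.idx(i, j, k);
          double exm = fx(i - 1, j, k), exp_ = fx(i, j, k);
          double eym = fy(i, j - 1, k), eyp = fy(i, j, k);
          double ezm = fz(i, j, k - 1), ezp = fz(i, j, k);
          double den = exm + exp_ + eym + eyp + ezm + ezp + diag_extra[c];
          double num = exm * phi[g.idx(i - 1, j, k)] + exp_ * phi[g.idx(i + 1, j, k)] +
                       eym * phi[g.idx(i, j - 1, k)] + eyp * phi[g.idx(i, j + 1, k)] +
                       ezm * phi[g.idx(i, j, k - 1)] + ezp * phi[g.idx(i, j, k + 1)] +
                       src[c];
          double nphi = (1.0 - omega) * phi[c] + omega * num / den;
          double d = std::fabs(nphi - phi[c]);
          if (d > maxdiff) maxdiff = d;
          phi[c] = nphi;
        }
    if (maxdiff < thresh) return it;
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return -1;
}

// Edge-centered dielectric with a smoothed interface: for each edge
// midpoint the signed distance to the solute surface (min over atoms of
// |x - c_a| - r_a) sets an inside fraction f = clamp(1/2 - d/h, 0, 1)
// (linear window one grid cell wide), and the edge dielectric is the
// harmonic mean 1/eps = f/eps_in + (1-f)/eps_out. The window shrinks with
// the grid, so the energy converges smoothly to the sharp-boundary limit.
// Also marks nodes inside the solute.
static void build_dielectric(const Grid &g, const NumericMatrix &pos,
                             const NumericVector &rad, double eps_in,
                             double eps_out, std::vector<double> &ex,
                             std::vector<double> &ey, std::vector<double> &ez,
                             std::vector<char> &inside_node) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const double big = 1e30;
  std::vector<double> dx_((size_t)(nx - 1) * ny * nz, big);
  std::vector<double> dy_((size_t)nx * (ny - 1) * nz, big);
  std::vector<double> dz_((size_t)nx * ny * (nz - 1), big);
  inside_node.assign((size_t)nx * ny * nz, 0);
  // reach: surface distance matters within half a window (h) of the surface
  for (int a = 0; a < pos.nrow(); ++a) {
    double r = rad[a];
    if (r <= 0) continue;
    double reach = r + 2.0 * g.h;
    double px = pos(a, 0), py = pos(a, 1), pz = pos(a, 2);
    int i0 = std::max(0, (int)std::floor((px - reach - g.ox) / g.h) - 1);
    int i1 = std::min(nx - 1, (int)std::ceil((px + reach - g.ox) / g.h) + 1);
    int j0 = std::max(0, (int)std::floor((py - reach - g.oy) / g.h) - 1);
    int j1 = std::min(ny - 1, (int)std::ceil((py + reach - g.oy) / g.h) + 1);
    int k0 = std::max(0, (int)std::floor((pz - reach - g.oz) / g.h) - 1);
    int k1 = std::min(nz - 1, (int)std::ceil((pz + reach - g.oz) / g.h) + 1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double x = g.ox + i * g.h, y = g.oy + j * g.h, z = g.oz + k * g.h;
          double ddx = x - px, ddy = y - py, ddz = z - pz;
          if (ddx * ddx + ddy * ddy + ddz * ddz <= r * r)
            inside_node[g.idx(i, j, k)] = 1;
          if (i < nx - 1) {
            size_t e = (size_t)i + (size_t)(nx - 1) * ((size_t)j + (size_t)ny * k);
            double mx = ddx + 0.5 * g.h;
            double d = std::sqrt(mx * mx + ddy * ddy + ddz * ddz) - r;
            if (d < dx_[e]) dx_[e] = d;
          }
          if (j < ny - 1) {
            size_t e = (size_t)i + (size_t)nx * ((size_t)j + (size_t)(ny - 1) * k);
            double my = ddy + 0.5 * g.h;
            double d = std::sqrt(ddx * ddx + my * my + ddz * ddz) - r;
            if (d < dy_[e]) dy_[e] = d;
          }
          if (k < nz - 1) {
            size_t e = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
            double mz = ddz + 0.5 * g.h;
            double d = std::sqrt(ddx * ddx + ddy * ddy + mz * mz) - r;
            if (d < dz_[e]) dz_[e] = d;
          }
        }
  }
  auto smooth = [&](double d) {
    double f = 0.5 - d / g.h;
    if (f < 0) f = 0;
    if (f > 1) f = 1;
    return 1.0 / (f / eps_in + (1.0 - f) / eps_out);
  };
  ex.resize(dx_.size()); ey.resize(dy_.size()); ez.resize(dz_.size());
  for (size_t t = 0; t < dx_.size(); ++t) ex[t] = smooth(dx_[t]);
  for (size_t t = 0; t < dy_.size(); ++t) ey[t] = smooth(dy_[t]);
  for (size_t t = 0; t < dz_.size(); ++t) ez[t] = smooth(dz_[t]);
}

static void spread_charges(const Grid &g, const NumericMatrix &pos,
                           const NumericVector &q, std::vector<double> &qnode) {
  qnode.assign((size_t)g.nx * g.ny * g.nz, 0.0);
  for (int a = 0; a < pos.nrow(); ++a) {
    double gx = (pos(a, 0) - g.ox) / g.h;
    double gy = (pos(a, 1) - g.oy) / g.h;
    double gz = (pos(a, 2) - g.oz) / g.h;
    int i = (int)std::floor(gx), j = (int)std::floor(gy), k = (int)std::floor(gz);
    if (i < 0 || j < 0 || k < 0 || i >= g.nx - 1 || j >= g.ny - 1 || k >= g.nz - 1)
      stop("atom %d outside PB grid", a + 1);
    double fx = gx - i, fy = gy - j, fz = gz - k;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          qnode[g.idx(i + di, j + dj, k + dk)] += w * q[a];
        }
  }
}

static void dirichlet_boundary(const Grid &g, const NumericMatrix &pos,
                               const NumericVector &q, double eps,
                               double kappa, std::vector<double> &phi) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  auto bval = [&](int i, int j, int k) {
    double x = g.ox + i * g.h, y = g.oy + j * g.h, z = g.oz + k * g.h;
    double v = 0.0;
    for (int a = 0; a < pos.nrow(); ++a) {
      double dx = x - pos(a, 0), dy = y - pos(a, 1), dz = z - pos(a, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-9) r = 1e-9;
      double s = kappa > 0 ? std::exp(-kappa * r) : 1.0;
      v += FPB * q[a] * s / (eps * r);
    }
    return v;
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1)
          phi[g.idx(i, j, k)] = bval(i, j, k);
}

static double interp_phi(const Grid &g, const std::vector<double> &phi,
                         double x, double y, double z) {
  double gx = (x - g.ox) / g.h, gy = (y - g.oy) / g.h, gz = (z - g.oz) / g.h;
  int i = (int)std::floor(gx), j = (int)std::floor(gy), k = (int)std::floor(gz);
  double fx = gx - i, fy = gy - j, fz = gz - k;
  double v = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di)
        v += (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz) *
             phi[g.idx(i + di, j + dj, k + dk)];
  return v;
}

// [[Rcpp::export(name = ".cpp_pb_solvation")]]
List cpp_pb_solvation(NumericMatrix pos, NumericVector q, NumericVector rad,
                      double grid_spacing, double margin, double eps_in,
                      double eps_out, double kappa, int maxiter, double tol) {
  if (pos.nrow() == 0) stop("PB solve needs at least one atom");
  Grid g;
  g.h = grid_spacing;
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = R_PosInf; hi[k] = R_NegInf;
    for (int a = 0; a < pos.nrow(); ++a) {
      lo[k] = std::min(lo[k], pos(a, k) - rad[a]);
      hi[k] = std::max(hi[k], pos(a, k) + rad[a]);
    }
    lo[k] -= margin; hi[k] += margin;
  }
  g.nx = (int)std::ceil((hi[0] - lo[0]) / g.h) + 1;
  g.ny = (int)std::ceil((hi[1] - lo[1]) / g.h) + 1;
  g.nz = (int)std::ceil((hi[2] - lo[2]) / g.h) + 1;
  g.ox = lo[0] - 0.5 * (g.h * (g.nx - 1) - (hi[0] - lo[0]));
  g.oy = lo[1] - 0.5 * (g.h * (g.ny - 1) - (hi[1] - lo[1]));
  g.oz = lo[2] - 0.5 * (g.h * (g.nz - 1) - (hi[2] - lo[2]));

  std::vector<double> ex, ey, ez, qnode;
  std::vector<char> inside;
  build_dielectric(g, pos, rad, eps_in, eps_out, ex, ey, ez, inside);
  spread_charges(g, pos, q, qnode);
  size_t ntot = (size_t)g.nx * g.ny * g.nz;
  // source term: 4 pi f q_node / h  (from integrating rho over the cell)
  std::vector<double> src(ntot, 0.0), diag_extra(ntot, 0.0);
  for (size_t t = 0; t < ntot; ++t)
    src[t] = FOUR_PI * FPB * qnode[t] / g.h;
  if (kappa > 0) {
    double kk = eps_out * kappa * kappa * g.h * g.h;
    for (size_t t = 0; t < ntot; ++t)
      if (!inside[t]) diag_extra[t] = kk;
  }

  std::vector<double> phi_het(ntot, 0.0), phi_hom(ntot, 0.0);
  dirichlet_boundary(g, pos, q, eps_out, kappa, phi_het);
  int it1 = sor_solve(g, ex, ey, ez, src, diag_extra, phi_het, maxiter, tol);
  if (it1 < 0)
    stop("PB solver did not converge within %d iterations", maxiter);
  // homogeneous reference: eps_in everywhere, no screening
  std::vector<double> exh((size_t)(g.nx - 1) * g.ny * g.nz, eps_in);
  std::vector<double> eyh((size_t)g.nx * (g.ny - 1) * g.nz, eps_in);
  std::vector<double> ezh((size_t)g.nx * g.ny * (g.nz - 1), eps_in);
  std::vector<double> zero_extra(ntot, 0.0);
  dirichlet_boundary(g, pos, q, eps_in, 0.0, phi_hom);
  int it2 = sor_solve(g, exh, eyh, ezh, src, zero_extra, phi_hom, maxiter, tol);
  if (it2 < 0)
    stop("PB reference solve did not converge within %d iterations", maxiter);

  NumericVector per_atom(pos.nrow());
  double energy = 0.0;
  for (int a = 0; a < pos.nrow(); ++a) {
    double dphi = interp_phi(g, phi_het, pos(a, 0), pos(a, 1), pos(a, 2)) -
                  interp_phi(g, phi_hom, pos(a, 0), pos(a, 1), pos(a, 2));
    per_atom[a] = 0.5 * q[a] * dphi;
    energy += per_atom[a];
  }
  return List::create(_["energy"] = energy, _["per_atom"] = per_atom,
                      _["iterations"] = IntegerVector::create(it1, it2),
                      _["grid_dim"] = IntegerVector::create(g.nx, g.ny, g.nz));
}
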