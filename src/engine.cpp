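// MD engine core: bonded + nonbonded forces with minimum-image periodic
// boundaries, velocity-Verlet integration with an optional Langevin (BAOAB)
// thermostat, and the oscillating-field coupling F_i = q_i E(t).
// Units: nm, ps, u, e, kJ/mol (1 u nm^2/ps^2 = 1 kJ/mol).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const double COULOMB = 138.935458;   // kJ mol^-1 nm e^-2
static const double EV_KJMOL = 96.4853;     // 1 e*V in kJ/mol
static const double TWO_PI = 6.283185307179586476925286766559;

// --- deterministic RNG (splitmix64 -> xoshiro256++), fixed draw order ------
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double normal() {  // Box-Muller, two uniforms per draw
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(TWO_PI * u2);
  }
};

struct System {
  int n;
  std::vector<double> x, v, m, q, sig, eps;
  double box;
  // bonds: i, j, kb, r0
  std::vector<int> b_i, b_j;
  std::vector<double> b_kb, b_r0;
  // angles: i, j(center), k, ka, theta0
  std::vector<int> a_i, a_j, a_k;
  std::vector<double> a_ka, a_th0;
  // double-well pairs: i, j, a4, r0, b, d
  std::vector<int> w_i, w_j;
  std::vector<double> w_a4, w_r0, w_b, w_d;
  std::unordered_set<int64_t> excl;
  inline bool excluded(int i, int j) const {
    int a = i < j ? i : j, b2 = i < j ? j : i;
    return excl.count((int64_t)a * n + b2) > 0;
  }
};

static inline double min_image(double dx, double box) {
  return dx - box * std::nearbyint(dx / box);
}

static System build_system(const NumericMatrix &pos, const NumericMatrix &vel,
                           const NumericVector &mass, const NumericVector &charge,
                           const NumericVector &sigma, const NumericVector &epsv,
                           double box,
                           const IntegerMatrix &bonds_idx, const NumericMatrix &bonds_par,
                           const IntegerMatrix &ang_idx, const NumericMatrix &ang_par,
                           const IntegerMatrix &dw_idx, const NumericMatrix &dw_par,
                           const IntegerMatrix &excl) {
  System s;
  s.n = pos.nrow();
  s.box = box;
  s.x.resize(3 * s.n); s.v.resize(3 * s.n);
  s.m.assign(mass.begin(), mass.end());
  s.q.assign(charge.begin(), charge.end());
  s.sig.assign(sigma.begin(), sigma.end());
  s.eps.assign(epsv.begin(), epsv.end());
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) {
      s.x[3 * i + k] = pos(i, k);
      s.v[3 * i + k] = vel(i, k);
    }
  for (int b = 0; b < bonds_idx.nrow(); ++b) {
    s.b_i.push_back(bonds_idx(b, 0) - 1);
    s.b_j.push_back(bonds_idx(b, 1) - 1);
    s.b_kb.push_back(bonds_par(b, 0));
    s.b_r0.push_back(bonds_par(b, 1));
  }
  for (int a = 0; a < ang_idx.nrow(); ++a) {
    s.a_i.push_back(ang_idx(a, 0) - 1);
    s.a_j.push_back(ang_idx(a, 1) - 1);
    s.a_k.push_back(ang_idx(a, 2) - 1);
    s.a_ka.push_back(ang_par(a, 0));
    s.a_th0.push_back(ang_par(a, 1));
  }
  for (int w = 0; w < dw_idx.nrow(); ++w) {
    s.w_i.push_back(dw_idx(w, 0) - 1);
    s.w_j.push_back(dw_idx(w, 1) - 1);
    s.w_a4.push_back(dw_par(w, 0));
    s.w_r0.push_back(dw_par(w, 1));
    s.w_b.push_back(dw_par(w, 2));
    s.w_d.push_back(dw_par(w, 3));
  }
  for (int e = 0; e < excl.nrow(); ++e) {
    int a = excl(e, 0) - 1, b2 = excl(e, 1) - 1;
    if (a > b2) std::swap(a, b2);
    s.excl.insert((int64_t)a * s.n + b2);
  }
  return s;
}

struct EnergyParts {
  double bond = 0, angle = 0, pair_dw = 0, lj = 0, coulomb = 0, field = 0;
  double total() const { return bond + angle + pair_dw + lj + coulomb + field; }
};

// forces (overwritten) and potential energy components at coordinates s.x
static EnergyParts compute_forces_core(const System &s, double cutoff,
                                       std::vector<double> &f,
                                       bool use_field, double fA, double fnu,
                                       double fphi, const double *fu, double t) {
  EnergyParts ep;
  const int n = s.n;
  std::fill(f.begin(), f.end(), 0.0);
  const double rc2 = cutoff * cutoff;

  // bonds
  for (size_t b = 0; b < s.b_i.size(); ++b) {
    int i = s.b_i[b], j = s.b_j[b];
    double d[3], r2 = 0;
    for (int k = 0; k < 3; ++k) {
      d[k] = min_image(s.x[3 * i + k] - s.x[3 * j + k], s.box);
      r2 += d[k] * d[k];
    }
    double r = std::sqrt(r2);
    double fr;
    if (r < 1e-6) {
      // a zero-rest-length bond is a regular isotropic spring at the origin
      if (s.b_r0[b] == 0.0) {
        ep.bond += 0.5 * s.b_kb[b] * r2;
        fr = -s.b_kb[b];
        for (int k = 0; k < 3; ++k) {
          f[3 * i + k] += fr * d[k];
          f[3 * j + k] -= fr * d[k];
        }
        continue;
      }
      stop("singularity: bonded atoms %d and %d overlap", i + 1, j + 1);
    }
    double dr = r - s.b_r0[b];
    ep.bond += 0.5 * s.b_kb[b] * dr * dr;
    fr = -s.b_kb[b] * dr / r;  // dV/dr * (-1/r) factor applied below
    for (int k = 0; k < 3; ++k) {
      f[3 * i + k] += fr * d[k];
      f[3 * j + k] -= fr * d[k];
    }
  }

  // double-well pairs: V(z) = a4 (z^4 - 4/3 (b+d) z^3 + 2 b d z^2), z = r - r0
  for (size_t w = 0; w < s.w_i.size(); ++w) {
    int i = s.w_i[w], j = s.w_j[w];
    double d[3], r2 = 0;
    for (int k = 0; k < 3; ++k) {
      d[k] = min_image(s.x[3 * i + k] - s.x[3 * j + k], s.box);
      r2 += d[k] * d[k];
    }
    double r = std::sqrt(r2);
    if (r < 1e-6) stop("singularity: double-well pair %d-%d overlaps", i + 1, j + 1);
    double z = r - s.w_r0[w], bb = s.w_b[w], dd = s.w_d[w], a4 = s.w_a4[w];
    ep.pair_dw += a4 * (z * z * z * z - (4.0 / 3.0) * (bb + dd) * z * z * z +
                        2.0 * bb * dd * z * z);
    double dVdr = 4.0 * a4 * z * (z - bb) * (z - dd);
    double fr = -dVdr / r;
    for (int k = 0; k < 3; ++k) {
      f[3 * i + k] += fr * d[k];
      f[3 * j + k] -= fr * d[k];
    }
  }

  // angles (harmonic in theta around central atom j)
  for (size_t a = 0; a < s.a_i.size(); ++a) {
    int i = s.a_i[a], j = s.a_j[a], k2 = s.a_k[a];
    double u[3], w[3];
    double nu2 = 0, nw2 = 0, dot = 0;
    for (int k = 0; k < 3; ++k) {
      u[k] = min_image(s.x[3 * i + k] - s.x[3 * j + k], s.box);
      w[k] = min_image(s.x[3 * k2 + k] - s.x[3 * j + k], s.box);
      nu2 += u[k] * u[k];
      nw2 += w[k] * w[k];
      dot += u[k] * w[k];
    }
    double nu = std::sqrt(nu2), nw = std::sqrt(nw2);
    double c = dot / (nu * nw);
    c = std::max(-1.0, std::min(1.0, c));
    double sth = std::sqrt(std::max(1.0 - c * c, 1e-12));
    double th = std::acos(c);
    double dth = th - s.a_th0[a];
    ep.angle += 0.5 * s.a_ka[a] * dth * dth;
    double coeff = s.a_ka[a] * dth / sth;  // (dV/dtheta)/sin(theta)
    for (int k = 0; k < 3; ++k) {
      double dci = w[k] / (nu * nw) - c * u[k] / nu2;
      double dck = u[k] / (nu * nw) - c * w[k] / nw2;
      double fi = coeff * dci, fk = coeff * dck;
      f[3 * i + k] += fi;
      f[3 * k2 + k] += fk;
      f[3 * j + k] -= (fi + fk);
    }
  }

  // nonbonded: LJ (Lorentz-Berthelot) + truncated Coulomb, minimum image
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (s.excluded(i, j)) continue;
      bool has_lj = s.eps[i] > 0 && s.eps[j] > 0;
      bool has_q = s.q[i] != 0 && s.q[j] != 0;
      if (!has_lj && !has_q) continue;
      double d[3], r2 = 0;
      for (int k = 0; k < 3; ++k) {
        d[k] = min_image(s.x[3 * i + k] - s.x[3 * j + k], s.box);
        r2 += d[k] * d[k];
      }
      if (r2 > rc2) continue;
      if (r2 < 1e-12)
        stop("singularity: nonbonded atoms %d and %d overlap", i + 1, j + 1);
      double fr = 0;
      if (has_lj) {
        double sij = 0.5 * (s.sig[i] + s.sig[j]);
        double eij = std::sqrt(s.eps[i] * s.eps[j]);
        double sr2 = sij * sij / r2;
        double sr6 = sr2 * sr2 * sr2;
        ep.lj += 4.0 * eij * sr6 * (sr6 - 1.0);
        fr += 24.0 * eij * sr6 * (2.0 * sr6 - 1.0) / r2;
      }
      if (has_q) {
        double r = std::sqrt(r2);
        double e = COULOMB * s.q[i] * s.q[j] / r;
        ep.coulomb += e;
        fr += e / r2;
      }
      for (int k = 0; k < 3; ++k) {
        f[3 * i + k] += fr * d[k];
        f[3 * j + k] -= fr * d[k];
      }
    }
  }

  // oscillating field: F_i = q_i E(t); bookkeeping energy -sum q_i E(t).x_i
  if (use_field && fA > 0) {
    double c = fA * std::cos(TWO_PI * fnu * t + fphi) * EV_KJMOL;
    for (int i = 0; i < n; ++i) {
      if (s.q[i] == 0) continue;
      double qc = s.q[i] * c;
      for (int k = 0; k < 3; ++k) {
        f[3 * i + k] += qc * fu[k];
        ep.field -= qc * fu[k] * s.x[3 * i + k];
      }
    }
  }
  return ep;
}

// [[Rcpp::export(name = ".cpp_compute_forces")]]
List cpp_compute_forces(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                        NumericVector charge, NumericVector sigma, NumericVector epsv,
                        double box, IntegerMatrix bonds_idx, NumericMatrix bonds_par,
                        IntegerMatrix ang_idx, NumericMatrix ang_par,
                        IntegerMatrix dw_idx, NumericMatrix dw_par,
                        IntegerMatrix excl, double cutoff,
                        bool use_field, double fA, double fnu, double fphi,
                        NumericVector fu, double t) {
  System s = build_system(pos, vel, mass, charge, sigma, epsv, box, bonds_idx,
                          bonds_par, ang_idx, ang_par, dw_idx, dw_par, excl);
  std::vector<double> f(3 * s.n);
  double u3[3] = {0, 0, 1};
  if (fu.size() == 3) { u3[0] = fu[0]; u3[1] = fu[1]; u3[2] = fu[2]; }
  EnergyParts ep = compute_forces_core(s, cutoff, f, use_field, fA, fnu, fphi, u3, t);
  NumericMatrix fm(s.n, 3);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) fm(i, k) = f[3 * i + k];
  return List::create(
      _["forces"] = fm,
      _["potential_energy"] = ep.total(),
      _["components"] = NumericVector::create(
          _["bond"] = ep.bond, _["angle"] = ep.angle, _["pair_dw"] = ep.pair_dw,
          _["lj"] = ep.lj, _["coulomb"] = ep.coulomb,
          _["field_coupling"] = ep.field));
}

// [[Rcpp::export(name = ".cpp_integrate")]]
List cpp_integrate(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                   NumericVector charge, NumericVector sigma, NumericVector epsv,
                   double box, IntegerMatrix bonds_idx, NumericMatrix bonds_par,
                   IntegerMatrix ang_idx, NumericMatrix ang_par,
                   IntegerMatrix dw_idx, NumericMatrix dw_par,
                   IntegerMatrix excl, double cutoff,
                   bool use_field, double fA, double fnu, double fphi,
                   NumericVector fu,
                   double dt, int n_steps, bool langevin, double gamma,
                   double temperature, int seed, int sample_every) {
  System s = build_system(pos, vel, mass, charge, sigma, epsv, box, bonds_idx,
                          bonds_par, ang_idx, ang_par, dw_idx, dw_par, excl);
  const int n = s.n;
  double u3[3] = {0, 0, 1};
  if (fu.size() == 3) { u3[0] = fu[0]; u3[1] = fu[1]; u3[2] = fu[2]; }
  const double kB = 0.0083144621;
  Rng rng((uint64_t)seed);
  const double c1 = langevin ? std::exp(-gamma * dt) : 1.0;
  const double c2 = langevin ? std::sqrt(std::max(0.0, 1.0 - c1 * c1)) : 0.0;
  std::vector<double> sdv(n);  // per-atom thermal velocity scale
  for (int i = 0; i < n; ++i) sdv[i] = std::sqrt(kB * temperature / s.m[i]);

  const int n_frames = n_steps / sample_every + 1;
  NumericVector times(n_frames), epot(n_frames), ekin(n_frames);
  NumericVector pos_out(n_frames * n * 3), vel_out(n_frames * n * 3);

  std::vector<double> f(3 * n);
  EnergyParts ep = compute_forces_core(s, cutoff, f, use_field, fA, fnu, fphi,
                                       u3, 0.0);
  int fr = 0;
  auto record = [&](int step, const EnergyParts &e) {
    times[fr] = step * dt;
    double ke = 0;
    for (int i = 0; i < n; ++i) {
      double v2 = 0;
      for (int k = 0; k < 3; ++k) {
        double xi = s.x[3 * i + k], vi = s.v[3 * i + k];
        if (!std::isfinite(xi) || !std::isfinite(vi))
          stop("divergence: non-finite coordinate/velocity at step %d", step);
        // layout [frame, atom, dim] in column-major R array terms
        pos_out[fr + n_frames * (i + (int64_t)n * k)] = xi;
        vel_out[fr + n_frames * (i + (int64_t)n * k)] = vi;
        v2 += vi * vi;
      }
      ke += 0.5 * s.m[i] * v2;
    }
    epot[fr] = e.total();
    ekin[fr] = ke;
    ++fr;
  };
  record(0, ep);

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        s.v[3 * i + k] += 0.5 * dt * f[3 * i + k] / s.m[i];
    // A: half drift
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        s.x[3 * i + k] += 0.5 * dt * s.v[3 * i + k];
    // O: Ornstein-Uhlenbeck velocity update (identity when gamma = 0)
    if (langevin) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          s.v[3 * i + k] = c1 * s.v[3 * i + k] + c2 * sdv[i] * rng.normal();
    }
    // A: half drift
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        s.x[3 * i + k] += 0.5 * dt * s.v[3 * i + k];
    // force at new positions and time
    ep = compute_forces_core(s, cutoff, f, use_field, fA, fnu, fphi, u3,
                             step * dt);
    // B: half kick
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        s.v[3 * i + k] += 0.5 * dt * f[3 * i + k] / s.m[i];
    if (step % sample_every == 0) record(step, ep);
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  pos_out.attr("dim") = IntegerVector::create(n_frames, n, 3);
  vel_out.attr("dim") = IntegerVector::create(n_frames, n, 3);
  return List::create(_["times"] = times, _["positions"] = pos_out,
                      _["velocities"] = vel_out, _["potential"] = epot,
                      _["kinetic"] = ekin);
}
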