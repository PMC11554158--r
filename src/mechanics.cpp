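// Pairwise softcore Lennard-Jones kernels, packing-fraction estimator and
// velocity-Verlet integration. Hot loops of the simulator; everything here is
// deterministic and allocation-light.
//
// Softcore pair potential: U(r) = 4 eps [S^-2 - S^-1] with
//   S(r) = c_soft + (r/sij)^6,  sij = sigma_i + sigma_j,
// truncated at rcut = rcut_factor * zeta * sij and shifted so U(rcut) = 0.
// The minimum sits at r = zeta * sij (the sum of the two cell radii).
//
// Neighbor search: brute force for small N, cell-linked lists (bin size =
// the largest pair cutoff) otherwise. Both paths produce identical forces;
// the brute path is kept as the oracle in tests.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct CellList {
  int nx, ny, nz;
  double x0, y0, z0, h;
  std::vector<std::vector<int>> bins;

  CellList(const NumericMatrix& pos, double cutoff) {
    const int n = pos.nrow();
    double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
    double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, pos(i, 0)); xmax = std::max(xmax, pos(i, 0));
      ymin = std::min(ymin, pos(i, 1)); ymax = std::max(ymax, pos(i, 1));
      zmin = std::min(zmin, pos(i, 2)); zmax = std::max(zmax, pos(i, 2));
    }
    h = cutoff;
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = std::max(1, (int)std::floor((xmax - xmin) / h) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / h) + 1);
    nz = std::max(1, (int)std::floor((zmax - zmin) / h) + 1);
    bins.assign((size_t)nx * ny * nz, {});
    for (int i = 0; i < n; ++i) bins[index_of(pos, i)].push_back(i);
  }

  size_t index_of(const NumericMatrix& pos, int i) const {
    int ix = std::min(nx - 1, (int)std::floor((pos(i, 0) - x0) / h));
    int iy = std::min(ny - 1, (int)std::floor((pos(i, 1) - y0) / h));
    int iz = std::min(nz - 1, (int)std::floor((pos(i, 2) - z0) / h));
    return ((size_t)iz * ny + iy) * nx + ix;
  }
};

// Visit each unordered pair {i, j} whose separation can be below the largest
// pair cutoff; the kernel re-checks the exact pairwise cutoff.
template <typename Kernel>
void for_each_pair(const NumericMatrix& pos, double max_cutoff, int method,
                   Kernel kernel) {
  const int n = pos.nrow();
  const bool brute = (method == 1) || (method == 0 && n <= 200);
  if (brute) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) kernel(i, j);
    return;
  }
  CellList cl(pos, max_cutoff);
  for (int iz = 0; iz < cl.nz; ++iz)
    for (int iy = 0; iy < cl.ny; ++iy)
      for (int ix = 0; ix < cl.nx; ++ix) {
        const auto& a = cl.bins[((size_t)iz * cl.ny + iy) * cl.nx + ix];
        if (a.empty()) continue;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int jx = ix + dx, jy = iy + dy, jz = iz + dz;
              if (jx < 0 || jy < 0 || jz < 0 ||
                  jx >= cl.nx || jy >= cl.ny || jz >= cl.nz) continue;
              size_t bj = ((size_t)jz * cl.ny + jy) * cl.nx + jx;
              size_t bi = ((size_t)iz * cl.ny + iy) * cl.nx + ix;
              if (bj < bi) continue;  // each bin pair once
              const auto& b = cl.bins[bj];
              if (bj == bi) {
                for (size_t u = 0; u < a.size(); ++u)
                  for (size_t v = u + 1; v < a.size(); ++v)
                    kernel(a[u], a[v]);
              } else {
                for (int i : a)
                  for (int j : b) kernel(i, j);
              }
            }
      }
}

inline double max_sigma(const NumericVector& sigma) {
  double m = 0.0;
  for (double s : sigma) m = std::max(m, s);
  return m;
}

// dU/dr of the (unshifted) softcore potential.
inline double dU_dr(double d, double sij, double c_soft, double eps) {
  double s6 = std::pow(d / sij, 6);
  double S = c_soft + s6;
  double dUdS = 4.0 * eps * (-2.0 / (S * S * S) + 1.0 / (S * S));
  return dUdS * 6.0 * std::pow(d, 5) / std::pow(sij, 6);
}

inline double U_raw(double d, double sij, double c_soft, double eps) {
  double S = c_soft + std::pow(d / sij, 6);
  return 4.0 * eps * (1.0 / (S * S) - 1.0 / S);
}

void accumulate_forces(const NumericMatrix& pos, const NumericVector& sigma,
                       double c_soft, double zeta, double eps,
                       double rcut_factor, int method, NumericMatrix& f) {
  std::fill(f.begin(), f.end(), 0.0);
  double max_cut = rcut_factor * zeta * 2.0 * max_sigma(sigma);
  for_each_pair(pos, max_cut, method, [&](int i, int j) {
    double sij = sigma[i] + sigma[j];
    double rcut = rcut_factor * zeta * sij;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= rcut * rcut) return;
    double d = std::sqrt(d2);
    if (d == 0.0) return;  // direction undefined; softcore energy is finite
    double fr = -dU_dr(d, sij, c_soft, eps) / d;  // F = -dU/dr * rhat
    f(i, 0) += fr * dx; f(i, 1) += fr * dy; f(i, 2) += fr * dz;
    f(j, 0) -= fr * dx; f(j, 1) -= fr * dy; f(j, 2) -= fr * dz;
  });
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_pair_forces(const NumericMatrix& pos,
                              const NumericVector& sigma, double c_soft,
                              double zeta, double eps, double rcut_factor,
                              int method = 0) {
  NumericMatrix f(pos.nrow(), 3);
  accumulate_forces(pos, sigma, c_soft, zeta, eps, rcut_factor, method, f);
  return f;
}

// [[Rcpp::export]]
double cpp_total_potential(const NumericMatrix& pos,
                           const NumericVector& sigma, double c_soft,
                           double zeta, double eps, double rcut_factor,
                           int method = 0) {
  double u = 0.0;
  double max_cut = rcut_factor * zeta * 2.0 * max_sigma(sigma);
  for_each_pair(pos, max_cut, method, [&](int i, int j) {
    double sij = sigma[i] + sigma[j];
    double rcut = rcut_factor * zeta * sij;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= rcut * rcut) return;
    double d = std::sqrt(d2);
    u += U_raw(d, sij, c_soft, eps) - U_raw(rcut, sij, c_soft, eps);
  });
  return u;
}

// Packing fraction: rho_i = (1/12) sum_{j != i} exp(-(s_ij - 1)/delta) with
// s_ij = |r_i - r_j| / (radius_i + radius_j), radius = zeta * sigma,
// truncated at the mechanical cutoff. Calibrated so 12 touching neighbors
// (close packing) give rho = 1.
// [[Rcpp::export]]
NumericVector cpp_packing_fraction(const NumericMatrix& pos,
                                   const NumericVector& sigma, double zeta,
                                   double delta, double rcut_factor,
                                   int method = 0) {
  NumericVector rho(pos.nrow());
  double max_cut = rcut_factor * zeta * 2.0 * max_sigma(sigma);
  for_each_pair(pos, max_cut, method, [&](int i, int j) {
    double contact = zeta * (sigma[i] + sigma[j]);  // radius_i + radius_j
    double rcut = rcut_factor * contact;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= rcut * rcut) return;
    double s = std::sqrt(d2) / contact;
    double w = std::exp(-(s - 1.0) / delta) / 12.0;
    rho[i] += w;
    rho[j] += w;
  });
  return rho;
}

// Velocity-Verlet with semi-implicit Stokes drag, n_sub substeps of dt/n_sub:
//   v_half = v + (h/2) (F(r) - mu v) / m
//   r     += h v_half
//   v      = (v_half + (h/2) F(r_new) / m) / (1 + h mu / (2 m))
// For mu = 0 this is plain (symplectic) velocity Verlet; for F = 0 the speed
// decays by ((1-x)/(1+x))^k, x = mu h/(2m), i.e. exp(-mu t/m) + O(h^2).
// Aborts (ok = false) if any substep displacement exceeds half the smallest
// cell radius.
// [[Rcpp::export]]
List cpp_verlet(const NumericMatrix& pos0, const NumericMatrix& vel0,
                const NumericVector& sigma, double m0, double mu, double dt,
                int n_sub, double c_soft, double zeta, double eps,
                double rcut_factor, int method = 0) {
  const int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  NumericMatrix f(n, 3), vhalf(n, 3);
  const double h = dt / n_sub;
  double min_radius = R_PosInf;
  for (double s : sigma) min_radius = std::min(min_radius, zeta * s);
  const double disp_limit = 0.5 * min_radius;
  const double denom = 1.0 + h * mu / (2.0 * m0);
  double max_disp = 0.0;
  bool ok = true;

  accumulate_forces(pos, sigma, c_soft, zeta, eps, rcut_factor, method, f);
  for (int step = 0; step < n_sub && ok; ++step) {
    for (int i = 0; i < n; ++i) {
      double sp2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        vhalf(i, k) = vel(i, k) +
          0.5 * h * (f(i, k) - mu * vel(i, k)) / m0;
        sp2 += vhalf(i, k) * vhalf(i, k);
      }
      double disp = std::sqrt(sp2) * h;
      max_disp = std::max(max_disp, disp);
      if (disp > disp_limit) { ok = false; }
      for (int k = 0; k < 3; ++k) pos(i, k) += h * vhalf(i, k);
    }
    if (!ok) break;
    accumulate_forces(pos, sigma, c_soft, zeta, eps, rcut_factor, method, f);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        vel(i, k) = (vhalf(i, k) + 0.5 * h * f(i, k) / m0) / denom;
  }
  return List::create(_["pos"] = pos, _["vel"] = vel, _["ok"] = ok,
                      _["max_disp"] = max_disp, _["disp_limit"] = disp_limit);
}
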