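// Classical scattering trajectories of a buffer-gas pseudo-atom in the
// Lennard-Jones + ion-induced-dipole potential of a rigid molecule.
//
// Units: length angstrom, time ps, mass amu, charge e, energy eV.
// Acceleration = F[eV/A] / (mu[amu] * CONV), CONV = 1 amu (A/ps)^2 in eV.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double CONV = 1.03642697e-4;    // amu (A/ps)^2 -> eV
static const double COULOMB = 14.399645478;  // e^2/(4 pi eps0), eV*A

// Potential energy and force (on the probe) at position p.
static void energy_force(const double* cx, const double* cy, const double* cz,
                         const double* eps, const double* sig,
                         const double* q, int n, double alpha,
                         const double p[3], double& energy, double f[3]) {
  double e_lj = 0.0;
  double ex = 0.0, ey = 0.0, ez = 0.0;      // electric field, e/A^2
  double jxx = 0, jxy = 0, jxz = 0, jyy = 0, jyz = 0, jzz = 0;  // dE/dp
  f[0] = f[1] = f[2] = 0.0;
  bool charged = false;
  for (int i = 0; i < n; ++i) {
    const double dx = p[0] - cx[i];
    const double dy = p[1] - cy[i];
    const double dz = p[2] - cz[i];
    const double r2 = dx * dx + dy * dy + dz * dz;
    const double r = std::sqrt(r2);
    if (eps[i] > 0.0) {
      const double sr2 = sig[i] * sig[i] / r2;
      const double sr6 = sr2 * sr2 * sr2;
      const double sr12 = sr6 * sr6;
      e_lj += 4.0 * eps[i] * (sr12 - sr6);
      // dU/dr = 4 eps (-12 sr12 + 6 sr6)/r ; force = -dU/dr * rhat
      const double fr = 4.0 * eps[i] * (12.0 * sr12 - 6.0 * sr6) / r2;
      f[0] += fr * dx;
      f[1] += fr * dy;
      f[2] += fr * dz;
    }
    if (q[i] != 0.0) {
      charged = true;
      const double r3 = r2 * r;
      const double r5 = r3 * r2;
      ex += q[i] * dx / r3;
      ey += q[i] * dy / r3;
      ez += q[i] * dz / r3;
      const double a = q[i] / r3;
      const double b = 3.0 * q[i] / r5;
      jxx += a - b * dx * dx;
      jyy += a - b * dy * dy;
      jzz += a - b * dz * dz;
      jxy += -b * dx * dy;
      jxz += -b * dx * dz;
      jyz += -b * dy * dz;
    }
  }
  energy = e_lj;
  if (charged && alpha > 0.0) {
    const double e2 = ex * ex + ey * ey + ez * ez;
    energy += -0.5 * alpha * COULOMB * e2;
    // U = -(alpha/2) k |E|^2 ; grad U = -alpha k J^T E (J symmetric)
    // force = -grad U = alpha k J E
    f[0] += alpha * COULOMB * (jxx * ex + jxy * ey + jxz * ez);
    f[1] += alpha * COULOMB * (jxy * ex + jyy * ey + jyz * ez);
    f[2] += alpha * COULOMB * (jxz * ex + jyz * ey + jzz * ez);
  }
}

// [[Rcpp::export]]
List cpp_interaction_potential(NumericMatrix coords, NumericVector eps,
                               NumericVector sigma, NumericVector charges,
                               double alpha, NumericVector probe) {
  const int n = coords.nrow();
  std::vector<double> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = coords(i, 0);
    cy[i] = coords(i, 1);
    cz[i] = coords(i, 2);
    const double dx = probe[0] - cx[i];
    const double dy = probe[1] - cy[i];
    const double dz = probe[2] - cz[i];
    if (std::sqrt(dx * dx + dy * dy + dz * dz) < 0.1)
      stop("probe inside hard core of atom %d (r < 0.1 A)", i + 1);
  }
  double e;
  double f[3];
  double p[3] = {probe[0], probe[1], probe[2]};
  energy_force(cx.data(), cy.data(), cz.data(), eps.begin(), sigma.begin(),
               charges.begin(), n, alpha, p, e, f);
  return List::create(_["energy"] = e,
                      _["force"] = NumericVector::create(f[0], f[1], f[2]));
}

struct Deriv {
  const double *cx, *cy, *cz, *eps, *sig, *q;
  int n;
  double alpha, minv;  // minv = 1/(mu*CONV)
  void operator()(const double y[6], double dy[6]) const {
    double e, f[3];
    const double p[3] = {y[0], y[1], y[2]};
    energy_force(cx, cy, cz, eps, sig, q, n, alpha, p, e, f);
    dy[0] = y[3];
    dy[1] = y[4];
    dy[2] = y[5];
    dy[3] = f[0] * minv;
    dy[4] = f[1] * minv;
    dy[5] = f[2] * minv;
  }
};

// One Cash-Karp RK45 step with embedded 4th-order error estimate.
static void ck_step(const Deriv& d, const double y[6], double h,
                    double ynew[6], double yerr[6]) {
  static const double b21 = 1.0 / 5.0;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0,
                      b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double dc1 = c1 - 2825.0 / 27648.0,
                      dc3 = c3 - 18575.0 / 48384.0,
                      dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
                      dc6 = c6 - 0.25;
  double k1[6], k2[6], k3[6], k4[6], k5[6], k6[6], yt[6];
  d(y, k1);
  for (int i = 0; i < 6; ++i) yt[i] = y[i] + h * b21 * k1[i];
  d(yt, k2);
  for (int i = 0; i < 6; ++i) yt[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
  d(yt, k3);
  for (int i = 0; i < 6; ++i)
    yt[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
  d(yt, k4);
  for (int i = 0; i < 6; ++i)
    yt[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
  d(yt, k5);
  for (int i = 0; i < 6; ++i)
    yt[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                        b64 * k4[i] + b65 * k5[i]);
  d(yt, k6);
  for (int i = 0; i < 6; ++i) {
    ynew[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
    yerr[i] = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] + dc5 * k5[i] +
                   dc6 * k6[i]);
  }
}

// [[Rcpp::export]]
List cpp_propagate(NumericMatrix coords, NumericVector eps,
                   NumericVector sigma, NumericVector charges, double alpha,
                   double mu, NumericVector pos0, NumericVector vel0,
                   double error_tol, double energy_tol, int max_steps,
                   double r_escape) {
  const int n = coords.nrow();
  std::vector<double> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = coords(i, 0);
    cy[i] = coords(i, 1);
    cz[i] = coords(i, 2);
  }
  Deriv d{cx.data(), cy.data(), cz.data(),
          eps.begin(), sigma.begin(), charges.begin(),
          n, alpha, 1.0 / (mu * CONV)};

  const double v0n = std::sqrt(vel0[0] * vel0[0] + vel0[1] * vel0[1] +
                               vel0[2] * vel0[2]);
  double tol = error_tol;
  double chi = NA_REAL, drift = NA_REAL;
  bool escaped = false;
  int steps_used = 0;

  for (int attempt = 0; attempt < 3; ++attempt) {
    double y[6] = {pos0[0], pos0[1], pos0[2], vel0[0], vel0[1], vel0[2]};
    double e_pot, f[3];
    const double p0[3] = {y[0], y[1], y[2]};
    energy_force(cx.data(), cy.data(), cz.data(), eps.begin(), sigma.begin(),
                 charges.begin(), n, alpha, p0, e_pot, f);
    const double ke0 = 0.5 * mu * CONV *
                       (y[3] * y[3] + y[4] * y[4] + y[5] * y[5]);
    const double e0 = ke0 + e_pot;
    double h = 0.05 / std::max(v0n, 1e-8);  // ~0.05 A first step
    escaped = false;
    int steps = 0;
    while (steps < max_steps) {
      double ynew[6], yerr[6];
      ck_step(d, y, h, ynew, yerr);
      double err = 0.0;
      for (int i = 0; i < 6; ++i) {
        const double scale =
            std::fabs(y[i]) + std::fabs(h * (i < 3 ? y[i + 3] : 1.0)) + 1e-3;
        err = std::max(err, std::fabs(yerr[i]) / scale);
      }
      if (err <= tol) {
        for (int i = 0; i < 6; ++i) y[i] = ynew[i];
        ++steps;
        const double r = std::sqrt(y[0] * y[0] + y[1] * y[1] + y[2] * y[2]);
        const double out = y[0] * y[3] + y[1] * y[4] + y[2] * y[5];
        if (r >= r_escape && out > 0.0) {
          escaped = true;
          break;
        }
      }
      const double fac =
          std::min(5.0, std::max(0.2, 0.9 * std::pow(tol / std::max(err, 1e-16), 0.2)));
      h *= fac;
    }
    steps_used = steps;
    if (!escaped) break;
    const double pe[3] = {y[0], y[1], y[2]};
    energy_force(cx.data(), cy.data(), cz.data(), eps.begin(), sigma.begin(),
                 charges.begin(), n, alpha, pe, e_pot, f);
    const double ke = 0.5 * mu * CONV *
                      (y[3] * y[3] + y[4] * y[4] + y[5] * y[5]);
    drift = std::fabs(ke + e_pot - e0) / std::max(std::fabs(e0), 1e-12);
    const double vn = std::sqrt(y[3] * y[3] + y[4] * y[4] + y[5] * y[5]);
    double cosang = (vel0[0] * y[3] + vel0[1] * y[4] + vel0[2] * y[5]) /
                    std::max(v0n * vn, 1e-300);
    cosang = std::max(-1.0, std::min(1.0, cosang));
    chi = std::acos(cosang);
    if (drift <= energy_tol) break;
    tol *= 0.01;  // re-integrate with tighter step control
  }

  return List::create(_["chi"] = chi, _["escaped"] = escaped,
                      _["energy_drift"] = drift, _["n_steps"] = steps_used);
}
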