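#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Velocity-Verlet propagation of point charges under pairwise Coulomb forces.
//
// Units: position angstrom, velocity angstrom/fs, mass amu, charge e,
// time fs.  k_coul converts q1*q2/r to eV; ke_fac converts amu*(A/fs)^2 to
// eV, so the equations of motion read  m * ke_fac * dv/dt = F[eV/A].
//
// Far from the interaction region the dynamics are smooth, so once the
// smallest pair separation exceeds r_adapt the step is allowed to grow
// proportionally to that separation (capped at dt_max); this reaches the
// Coulomb asymptote (residual potential < resid_frac of the accumulated
// kinetic energy) in a bounded number of steps.

static void accelerations(const std::vector<double>& x,
                          const std::vector<double>& q,
                          const std::vector<double>& minv,
                          int n, double k_coul,
                          std::vector<double>& a,
                          double& pe, double& rmin) {
  std::fill(a.begin(), a.end(), 0.0);
  pe = 0.0;
  rmin = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (r < rmin) rmin = r;
      double qq = q[i] * q[j];
      if (qq == 0.0) continue;
      double e = k_coul * qq / r;
      pe += e;
      double f_over_r = e / r2;  // (k qq / r^2) / r
      double fx = f_over_r * dx, fy = f_over_r * dy, fz = f_over_r * dz;
      a[3 * i]     += fx * minv[i];
      a[3 * i + 1] += fy * minv[i];
      a[3 * i + 2] += fz * minv[i];
      a[3 * j]     -= fx * minv[j];
      a[3 * j + 1] -= fy * minv[j];
      a[3 * j + 2] -= fz * minv[j];
    }
  }
}

// [[Rcpp::export]]
List propagate_coulomb_cpp(NumericMatrix pos, NumericMatrix vel,
                           NumericVector mass, NumericVector charge,
                           double dt, double t_end,
                           bool to_asymptote, double resid_frac,
                           double r_adapt, double dt_max,
                           double k_coul, double ke_fac) {
  const int n = pos.nrow();
  std::vector<double> x(3 * n), v(3 * n), a(3 * n), q(n), m(n), minv(n);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = pos(i, d);
      v[3 * i + d] = vel(i, d);
    }
    q[i] = charge[i];
    m[i] = mass[i];
    minv[i] = 1.0 / (mass[i] * ke_fac);
  }

  double pe, rmin;
  accelerations(x, q, minv, n, k_coul, a, pe, rmin);

  auto kinetic = [&]() {
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      double v2 = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                  v[3 * i + 2] * v[3 * i + 2];
      ke += 0.5 * m[i] * v2 * ke_fac;
    }
    return ke;
  };

  const double e0 = kinetic() + pe;
  double drift_max = 0.0;
  double t = 0.0;
  long nsteps = 0;
  bool converged = !to_asymptote;

  while (t < t_end) {
    double h = dt;
    if (rmin > r_adapt) {
      h = dt * rmin / r_adapt;
      if (h > dt_max) h = dt_max;
    }
    if (t + h > t_end) h = t_end - t;

    for (int i = 0; i < 3 * n; ++i) {
      v[i] += 0.5 * h * a[i];
      x[i] += h * v[i];
    }
    accelerations(x, q, minv, n, k_coul, a, pe, rmin);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * h * a[i];

    t += h;
    ++nsteps;

    double ke = kinetic();
    double drift = std::fabs(ke + pe - e0);
    if (drift > drift_max) drift_max = drift;
    if (!std::isfinite(ke) || !std::isfinite(pe)) {
      stop("non-finite state during Coulomb propagation at step %ld (t = %g fs)",
           nsteps, t);
    }
    if (to_asymptote && std::fabs(pe) < resid_frac * ke && ke > 0.0) {
      converged = true;
      break;
    }
    if (nsteps % 1048576 == 0) checkUserInterrupt();
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      pos_out(i, d) = x[3 * i + d];
      vel_out(i, d) = v[3 * i + d];
    }
  }
  return List::create(
    _["pos"] = pos_out, _["vel"] = vel_out,
    _["t"] = t, _["n_steps"] = (double)nsteps,
    _["kinetic_eV"] = kinetic(), _["potential_eV"] = pe,
    _["energy_drift_eV"] = drift_max, _["e0_eV"] = e0,
    _["converged"] = converged);
}
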