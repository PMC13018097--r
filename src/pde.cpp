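#include <Rcpp.h>
using namespace Rcpp;

// Explicit finite-difference solvers for the four continuum systems:
//   U3: linear diffusion, explicit virus   P3: cross-diffusion, explicit virus
//   U2: linear diffusion, quasi-steady     P2: cross-diffusion, quasi-steady
// on a 1D chain (x arbitrary) or a radially symmetric 2D grid (r = j*dx).
//
// Linear diffusion: centred 3-point stencil; at the r = 0 node the
// radial Laplacian is closed by symmetry (L'Hopital): Lap(0) = 4(u1-u0)/dx^2.
// Cross-diffusion (D_P/K) d/dx [ u d/dx (u+i) ]: first-order donor-cell
// upwinding with shared face velocity V_{j+1/2} = -(D_P/K)(rho_{j+1}-rho_j)/dx
// for both species; radial form (1/r) d/dr (r u V) in conservative flux form
// with zero face flux at r = 0. No-flux boundaries everywhere.

// [[Rcpp::export]]
List pde_run_cpp(NumericVector u0, NumericVector i0, NumericVector v0,
                 double dx, double dt, int nsteps, int record_every,
                 bool radial, bool pressure, bool explicit_virus,
                 double p, double q, double q_v, double alpha, double beta_eff,
                 double K, double D_cell, double D_v) {
  const int n = u0.size();
  if (i0.size() != n || (explicit_virus && v0.size() != n))
    stop("field lengths differ");

  std::vector<double> u(u0.begin(), u0.end()), i(i0.begin(), i0.end());
  std::vector<double> v(explicit_virus ? n : 0);
  if (explicit_virus) std::copy(v0.begin(), v0.end(), v.begin());
  std::vector<double> un(n), in(n), vn(explicit_virus ? n : 0);
  std::vector<double> rho(n), Vface(n - 1);

  const int nrec = nsteps / record_every + 1;
  NumericMatrix recU(nrec, n), recI(nrec, n), recV(explicit_virus ? nrec : 0,
                                                   explicit_virus ? n : 0);
  NumericVector recT(nrec);
  NumericVector intU(nsteps + 1), intI(nsteps + 1);
  long clip_count = 0;
  double worst_under = 0.0;

  // integration weights: trapezoid; radial carries the 2*pi*r measure
  std::vector<double> w(n);
  for (int j = 0; j < n; ++j) {
    double base = (j == 0 || j == n - 1) ? 0.5 : 1.0;
    w[j] = radial ? base * 2.0 * M_PI * (j * dx) * dx : base * dx;
  }

  auto integrate = [&](const std::vector<double> &f) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += w[j] * f[j];
    return s;
  };

  auto record = [&](int slot, double t) {
    recT[slot] = t;
    for (int j = 0; j < n; ++j) {
      recU(slot, j) = u[j];
      recI(slot, j) = i[j];
      if (explicit_virus) recV(slot, j) = v[j];
    }
  };

  record(0, 0.0);
  intU[0] = integrate(u);
  intI[0] = integrate(i);
  int rslot = 1;
  const double dx2 = dx * dx;

  // linear diffusion operator (no-flux): returns Lap(f)[j]
  auto lap = [&](const std::vector<double> &f, int j) {
    double fm = (j > 0) ? f[j - 1] : f[j + 1];     // symmetry/no-flux ghost
    double fp = (j < n - 1) ? f[j + 1] : f[j - 1];
    if (!radial) {
      if (j == 0) fm = f[1];
      if (j == n - 1) fp = f[n - 2];
      return (fp + fm - 2.0 * f[j]) / dx2;
    }
    if (j == 0) return 4.0 * (f[1] - f[0]) / dx2; // 2 * f_rr by symmetry
    double lin = (fp + fm - 2.0 * f[j]) / dx2;
    double first = (fp - fm) / (2.0 * dx * (j * dx));
    return lin + first;
  };

  auto clipneg = [&](double &val) {
    if (val < 0.0) {
      if (val < worst_under) worst_under = val;
      val = 0.0;
      ++clip_count;
    }
  };

  for (int step = 0; step < nsteps; ++step) {
    double dd[2];
    if (pressure) {
      for (int j = 0; j < n; ++j) rho[j] = u[j] + i[j];
      for (int j = 0; j < n - 1; ++j)
        Vface[j] = -(D_cell / K) * (rho[j + 1] - rho[j]) / dx;
    }
    for (int j = 0; j < n; ++j) {
      if (pressure) {
        // donor-cell fluxes for u and i with the shared face velocity
        for (int sp = 0; sp < 2; ++sp) {
          const std::vector<double> &f = (sp == 0) ? u : i;
          double Fr = 0.0, Fl = 0.0;
          if (j < n - 1) {
            double V = Vface[j];
            Fr = (V > 0.0) ? f[j] * V : f[j + 1] * V;
          }
          if (j > 0) {
            double V = Vface[j - 1];
            Fl = (V > 0.0) ? f[j - 1] * V : f[j] * V;
          }
          if (!radial) {
            dd[sp] = -(Fr - Fl) / dx;
          } else if (j == 0) {
            // finite volume over [0, dx/2]: volume r dr = dx^2/8,
            // surface r_{1/2} F_r = (dx/2) Fr
            dd[sp] = -4.0 * Fr / dx;
          } else {
            double rp = (j + 0.5) * dx, rm = (j - 0.5) * dx;
            dd[sp] = -(rp * Fr - rm * Fl) / ((j * dx) * dx);
          }
        }
      } else {
        dd[0] = D_cell * lap(u, j);
        dd[1] = D_cell * lap(i, j);
      }
      double infect = explicit_virus ? beta_eff / K * u[j] * v[j]
                                     : beta_eff / K * u[j] * i[j];
      double growth = p * u[j] * (1.0 - (u[j] + i[j]) / K);
      un[j] = u[j] + dt * (dd[0] + growth - infect);
      in[j] = i[j] + dt * (dd[1] + infect - q * i[j]);
      clipneg(un[j]);
      clipneg(in[j]);
      if (explicit_virus) {
        vn[j] = v[j] + dt * (D_v * lap(v, j) + alpha * q * i[j] - q_v * v[j]);
        clipneg(vn[j]);
      }
    }
    u.swap(un);
    i.swap(in);
    if (explicit_virus) v.swap(vn);
    intU[step + 1] = integrate(u);
    intI[step + 1] = integrate(i);
    if ((step + 1) % record_every == 0 && rslot < nrec) {
      record(rslot, (step + 1) * dt);
      ++rslot;
    }
    if ((step & 4095) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector int_t(nsteps + 1);
  for (int s = 0; s <= nsteps; ++s) int_t[s] = s * dt;
  List out = List::create(
    _["times"] = recT, _["U"] = recU, _["I"] = recI,
    _["int_t"] = int_t, _["int_U"] = intU, _["int_I"] = intI,
    _["clip_count"] = (double) clip_count, _["worst_undershoot"] = worst_under);
  if (explicit_virus) out["v"] = recV;
  return out;
}
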