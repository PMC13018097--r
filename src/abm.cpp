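#include <Rcpp.h>
using namespace Rcpp;

// Hybrid lattice simulator: integer cell counts (uninfected U, infected I)
// on a 1D chain or 2D square lattice, coupled to a continuous viral
// concentration v updated by an explicit balance equation forced by the
// stochastic lysis events.
//
// One synchronous step, all event probabilities evaluated on the time-n state:
//   (1) lysis            L_j ~ Binomial(I_j, tau*q)
//   (2) infection        per uninfected cell, prob tau*beta*v_j/K
//   (3) demography       per remaining uninfected cell: divide w.p. tau*G+,
//                        die w.p. tau*G-, G(rho) = p*(1 - rho/K)
//   (4) movement         per cell, multinomial over neighbours + stay;
//                        F = theta/2 (1D) or theta/4 (2D) undirected,
//                        F = theta*(rho_j - rho_nb)+ / (2K or 4K) pressure
//   (5) virus            v' = v + tau*D_v*Lap(v) + alpha*L_j/delta^d
//                            - tau*q_v*v
// Boundaries are reflecting (zero-flux) for cells and virus.

static inline int rbinom_int(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  return (int) R::rbinom((double) n, p);
}

static inline void check_prob(double pr, const char *what) {
  if (pr > 1.0 + 1e-12 || pr < 0.0)
    stop("event probability out of [0,1] (%s: %g); reduce tau", what, pr);
}

// [[Rcpp::export]]
List abm_run_cpp(IntegerVector U0, IntegerVector I0, NumericVector v0,
                 int nx, int ny, double tau, double delta, int dimension,
                 double p, double q, double q_v, double alpha, double beta,
                 double K, double D_v, double theta, bool pressure,
                 int nsteps, int record_every) {
  const int n = nx * ny;
  if (U0.size() != n || I0.size() != n || v0.size() != n)
    stop("state vectors do not match the lattice size");
  const double meas = (dimension == 1) ? delta : delta * delta;
  const int ndir = (dimension == 1) ? 2 : 4;
  const double undirF = theta / ndir; // theta/2 (1D), theta/4 (2D)
  const double pressDen = (dimension == 1) ? 2.0 * K : 4.0 * K;
  const double dcoef = tau * D_v / (delta * delta);

  std::vector<int> U(U0.begin(), U0.end()), I(I0.begin(), I0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<int> Unew(n), Inew(n), L(n);
  std::vector<double> rho(n), vnew(n);

  const int nrec = nsteps / record_every + 1;
  IntegerMatrix recU(nrec, n), recI(nrec, n);
  NumericMatrix recV(nrec, n);
  NumericVector recT(nrec);
  NumericVector totU(nsteps + 1), totI(nsteps + 1), totV(nsteps + 1);

  // neighbour offsets; index -1 marks "outside" (reflecting: no attempt)
  auto neighbour = [&](int j, int d) -> int {
    int ix = j % nx, iy = j / nx;
    switch (d) {
      case 0: return (ix > 0)      ? j - 1  : -1;
      case 1: return (ix < nx - 1) ? j + 1  : -1;
      case 2: return (iy > 0)      ? j - nx : -1;
      default: return (iy < ny - 1) ? j + nx : -1;
    }
  };

  auto record = [&](int slot, double t) {
    recT[slot] = t;
    for (int j = 0; j < n; ++j) {
      recU(slot, j) = U[j];
      recI(slot, j) = I[j];
      recV(slot, j) = v[j];
    }
  };

  auto totals = [&](int step) {
    double su = 0, si = 0, sv = 0;
    for (int j = 0; j < n; ++j) { su += U[j]; si += I[j]; sv += v[j]; }
    totU[step] = su; totI[step] = si; totV[step] = sv * meas;
  };

  record(0, 0.0);
  totals(0);
  int rslot = 1;

  const double pq = tau * q;
  check_prob(pq, "lysis tau*q");

  for (int step = 0; step < nsteps; ++step) {
    for (int j = 0; j < n; ++j) rho[j] = (U[j] + I[j]) / meas;
    std::fill(Unew.begin(), Unew.end(), 0);
    std::fill(Inew.begin(), Inew.end(), 0);

    for (int j = 0; j < n; ++j) {
      // (1) lysis
      L[j] = rbinom_int(I[j], pq);
      int Irem = I[j] - L[j];

      // (2) infection
      int ninf = 0;
      if (U[j] > 0 && v[j] > 0.0) {
        double pinf = tau * beta * v[j] / K;
        check_prob(pinf, "infection tau*beta*v/K");
        ninf = rbinom_int(U[j], pinf);
      }
      int Urem = U[j] - ninf;
      Irem += ninf;

      // (3) demography
      if (Urem > 0) {
        double G = p * (1.0 - rho[j] / K);
        double pdem = tau * std::fabs(G);
        check_prob(pdem, "demography tau*|G|");
        int nev = rbinom_int(Urem, pdem);
        Urem += (G > 0) ? nev : -nev;
      }

      // (4) movement: multinomial via sequential conditional binomials,
      // probabilities from the time-n pressure field
      if (Urem > 0 || Irem > 0) {
        double F[4];
        double Fsum = 0.0;
        for (int d = 0; d < ndir; ++d) {
          int nb = neighbour(j, d);
          if (nb < 0) { F[d] = 0.0; continue; }
          if (pressure) {
            double dif = rho[j] - rho[nb];
            F[d] = (dif > 0.0) ? theta * dif / pressDen : 0.0;
          } else {
            F[d] = undirF;
          }
          Fsum += F[d];
        }
        check_prob(Fsum, "movement sum F");
        for (int pass = 0; pass < 2; ++pass) {
          int N = (pass == 0) ? Urem : Irem;
          std::vector<int> *dest = (pass == 0) ? &Unew : &Inew;
          if (N <= 0) { continue; }
          double remp = 1.0;
          for (int d = 0; d < ndir && N > 0; ++d) {
            if (F[d] <= 0.0) continue;
            double cp = F[d] / remp;
            int nm = rbinom_int(N, cp > 1.0 ? 1.0 : cp);
            if (nm > 0) (*dest)[neighbour(j, d)] += nm;
            N -= nm;
            remp -= F[d];
            if (remp <= 0.0) break;
          }
          (*dest)[j] += N; // stayers
        }
      }

    }

    // (5) virus: explicit diffusion + stochastic release - decay
    for (int j = 0; j < n; ++j) {
      double lap = 0.0;
      for (int d = 0; d < ndir; ++d) {
        int nb = neighbour(j, d);
        lap += ((nb >= 0) ? v[nb] : v[j]) - v[j];
      }
      vnew[j] = v[j] + dcoef * lap + alpha * L[j] / meas - tau * q_v * v[j];
      if (vnew[j] < 0.0) vnew[j] = 0.0; // guard against roundoff at tau*q_v ~ 1
    }

    U.swap(Unew);
    I.swap(Inew);
    v.swap(vnew);
    totals(step + 1);
    if ((step + 1) % record_every == 0 && rslot < nrec) {
      record(rslot, (step + 1) * tau);
      ++rslot;
    }
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector tot_t(nsteps + 1);
  for (int s = 0; s <= nsteps; ++s) tot_t[s] = s * tau;
  return List::create(
    _["times"] = recT, _["U"] = recU, _["I"] = recI, _["v"] = recV,
    _["tot_t"] = tot_t,
    _["tot_U"] = totU, _["tot_I"] = totI, _["tot_v"] = totV);
}
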