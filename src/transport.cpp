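#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Proton concentration at reaction equilibrium given the two quantities the
// phosphate and water reactions conserve at a node: total phosphate Ptot and
// Q = CH - COH - CP2. With CP2 = Ptot/(1 + CH/K) and COH = Kw/CH the balance
//   f(CH) = CH - Kw/CH - Ptot/(1 + CH/K) - Q = 0
// is strictly increasing in CH, so the root is unique. Newton iteration with
// a bisection safeguard on a bracketing interval.
static double equilibrium_CH(double Ptot, double Q, double Kw, double K,
                             double guess) {
  double lo = 1e-18, hi = 10.0 + std::fabs(Q) + Ptot;
  double ch = (guess > lo && guess < hi) ? guess : 1e-7;
  for (int it = 0; it < 200; ++it) {
    double u = 1.0 + ch / K;
    double f = ch - Kw / ch - Ptot / u - Q;
    if (f > 0.0) hi = ch; else lo = ch;
    double df = 1.0 + Kw / (ch * ch) + (Ptot / K) / (u * u);
    double chn = ch - f / df;
    if (!(chn > lo && chn < hi)) chn = 0.5 * (lo + hi);
    if (std::fabs(chn - ch) <= 1e-15 * ch) return chn;
    ch = chn;
  }
  return ch;
}

// [[Rcpp::export]]
double cpp_equilibrium_CH(double Ptot, double Q, double Kw, double K,
                          double guess) {
  return equilibrium_CH(Ptot, Q, Kw, K, guess);
}

// Explicit-Euler integration of the 1-D electro-diffusion-reaction system.
//
// State C is nodes x species in mol/L. Face fluxes use the Nernst-Planck
// expression with the electric term eliminated through the zero-current
// condition; within a layer the mobility factor beta multiplies the whole
// flux and cancels from the potential gradient. Internally fluxes are kept
// in (mol/L) cm s^-1; multiplying by 1e-3 gives mol cm^-2 s^-1.
//
// reaction_mode: 0 = no reactions, 1 = operator splitting with exact
// per-node equilibration, 2 = fully explicit with stability sub-stepping.
//
// watch_group: length-S integer vector; species sharing a positive group id
// have their fluxes summed and monitored for quasi-steady convergence: the
// summed flux at every face listed in monitor_faces must change by less
// than flux_tol (relative) per check interval. Monitoring the membrane
// interface faces in addition to the mid face matters: the initial
// condition is the linear (steady) membrane profile, so the mid-face flux
// alone is deceptively flat before the boundary transient reaches it.
//
// [[Rcpp::export]]
List cpp_run_transport(NumericMatrix C0, IntegerVector z, NumericVector D,
                       NumericVector beta_face, NumericVector h_face,
                       NumericVector cv,
                       double dt0, double t_max, double check_dt,
                       double flux_tol, int mid_face,
                       IntegerVector monitor_faces,
                       IntegerVector watch_group,
                       int reaction_mode, IntegerVector chem_idx,
                       double Kw, double K, double k1, double km1,
                       double kd, double kr, double C_H2O,
                       double max_steps) {
  const int N = C0.nrow(), S = C0.ncol(), NF = N - 1;
  std::vector<double> C(N * S), Cold(N * S), J(NF * S);
  std::vector<double> grad(S), cf(S);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < N; ++j) C[s * N + j] = C0(j, s);

  const int iH = chem_idx[0], iOH = chem_idx[1],
            iP1 = chem_idx[2], iP2 = chem_idx[3];
  const bool do_chem = reaction_mode > 0 && iH >= 0 && iOH >= 0;

  int n_groups = 0;
  for (int s = 0; s < S; ++s)
    if (watch_group[s] > n_groups) n_groups = watch_group[s];
  const int NM = monitor_faces.size();
  std::vector<double> Jwatch(n_groups * NM), Jwatch_prev(n_groups * NM);
  bool have_prev = false;

  std::vector<double> bnd_in(S, 0.0), bnd_out(S, 0.0);
  double t = 0.0, dt = dt0;
  double next_check = check_dt;
  double steps = 0.0;
  int rejects = 0;
  bool converged = false, failed = false;

  while (t < t_max && steps < max_steps) {
    // face fluxes
    for (int f = 0; f < NF; ++f) {
      double num = 0.0, den = 0.0;
      for (int s = 0; s < S; ++s) {
        const double cl = C[s * N + f], cr = C[s * N + f + 1];
        grad[s] = (cr - cl) / h_face[f];
        cf[s] = 0.5 * (cl + cr);
        if (z[s] != 0) {
          num += z[s] * D[s] * grad[s];
          den += double(z[s]) * z[s] * D[s] * cf[s];
        }
      }
      const double psi = (den > 0.0) ? -num / den : 0.0;
      for (int s = 0; s < S; ++s)
        J[s * NF + f] =
          -beta_face[f] * D[s] * (grad[s] + z[s] * cf[s] * psi);
    }

    Cold = C;
    // explicit Euler update of interior nodes
    bool bad = false;
    for (int s = 0; s < S; ++s) {
      const double *Js = &J[s * NF];
      double *Cs = &C[s * N];
      for (int j = 1; j < N - 1; ++j) {
        double cn = Cs[j] + dt * (Js[j - 1] - Js[j]) / cv[j];
        if (cn < 0.0) {
          if (cn > -1e-13) cn = 0.0;
          else { bad = true; break; }
        }
        Cs[j] = cn;
      }
      if (bad) break;
    }
    if (bad) {
      C = Cold;
      dt *= 0.5;
      if (++rejects > 40) { failed = true; break; }
      continue;
    }

    // reactions on interior nodes (boundaries are Dirichlet)
    if (do_chem) {
      if (reaction_mode == 1) {
        for (int j = 1; j < N - 1; ++j) {
          double CH = C[iH * N + j], COH = C[iOH * N + j];
          double P1 = (iP1 >= 0) ? C[iP1 * N + j] : 0.0;
          double P2 = (iP2 >= 0) ? C[iP2 * N + j] : 0.0;
          const double Ptot = P1 + P2;
          const double Q = CH - COH - P2;
          const double che = equilibrium_CH(Ptot, Q, Kw, K, CH);
          C[iH * N + j] = che;
          C[iOH * N + j] = Kw / che;
          if (iP1 >= 0) {
            C[iP1 * N + j] = Ptot / (1.0 + K / che);
            C[iP2 * N + j] = Ptot / (1.0 + che / K);
          }
        }
      } else {
        for (int j = 1; j < N - 1; ++j) {
          double CH = C[iH * N + j], COH = C[iOH * N + j];
          double P1 = (iP1 >= 0) ? C[iP1 * N + j] : 0.0;
          double P2 = (iP2 >= 0) ? C[iP2 * N + j] : 0.0;
          const double lambda =
            kr * (CH + COH) + km1 * (P2 + CH) + k1 + 1e-12;
          int nsub = (int)std::ceil(dt * lambda / 0.2);
          if (nsub < 1) nsub = 1;
          if (nsub > 200000) nsub = 200000;
          const double dts = dt / nsub;
          for (int m = 0; m < nsub; ++m) {
            const double rp = k1 * P1 - km1 * P2 * CH;
            const double rw = kd * C_H2O - kr * CH * COH;
            CH += dts * (rp + rw);
            COH += dts * rw;
            P1 -= dts * rp;
            P2 += dts * rp;
            if (CH < 0.0) CH = 0.0;
            if (COH < 0.0) COH = 0.0;
            if (P1 < 0.0) P1 = 0.0;
            if (P2 < 0.0) P2 = 0.0;
          }
          C[iH * N + j] = CH;
          C[iOH * N + j] = COH;
          if (iP1 >= 0) { C[iP1 * N + j] = P1; C[iP2 * N + j] = P2; }
        }
      }
    }

    // time-integrated boundary fluxes for conservation audits
    for (int s = 0; s < S; ++s) {
      bnd_in[s] += J[s * NF] * dt;
      bnd_out[s] += J[s * NF + NF - 1] * dt;
    }

    t += dt;
    steps += 1.0;

    if (t >= next_check) {
      std::fill(Jwatch.begin(), Jwatch.end(), 0.0);
      for (int m = 0; m < NM; ++m)
        for (int s = 0; s < S; ++s)
          if (watch_group[s] > 0)
            Jwatch[(watch_group[s] - 1) * NM + m] +=
              J[s * NF + monitor_faces[m]];
      if (have_prev) {
        bool ok = true;
        for (size_t k = 0; k < Jwatch.size(); ++k) {
          const double scale = std::max(std::fabs(Jwatch[k]), 1e-300);
          if (std::fabs(Jwatch[k] - Jwatch_prev[k]) / scale > flux_tol) {
            ok = false;
            break;
          }
        }
        if (ok && n_groups > 0) { converged = true; break; }
      }
      Jwatch_prev = Jwatch;
      have_prev = true;
      next_check += check_dt;
    }
  }

  NumericMatrix Cout(N, S), Jout(NF, S);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < N; ++j) Cout(j, s) = C[s * N + j];
    for (int f = 0; f < NF; ++f) Jout(f, s) = J[s * NF + f];
  }
  NumericVector Jmid(S), bin(S), bout(S);
  for (int s = 0; s < S; ++s) {
    Jmid[s] = J[s * NF + mid_face];
    bin[s] = bnd_in[s];
    bout[s] = bnd_out[s];
  }

  // electroneutrality diagnostic over nodes
  double max_imb = 0.0;
  for (int j = 0; j < N; ++j) {
    double qz = 0.0, qa = 0.0;
    for (int s = 0; s < S; ++s) {
      qz += z[s] * C[s * N + j];
      qa += std::fabs((double)z[s]) * C[s * N + j];
    }
    if (qa > 0.0) {
      const double r = std::fabs(qz) / qa;
      if (r > max_imb) max_imb = r;
    }
  }

  return List::create(_["C"] = Cout, _["J_faces"] = Jout, _["J_mid"] = Jmid,
                      _["t"] = t, _["steps"] = steps, _["dt"] = dt,
                      _["converged"] = converged, _["failed"] = failed,
                      _["rejects"] = rejects,
                      _["boundary_influx"] = bin,
                      _["boundary_outflux"] = bout,
                      _["max_charge_imbalance"] = max_imb);
}
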