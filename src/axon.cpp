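// Two-compartment (node + internode, Barrett-Barrett coupled) myelinated
// axon with 73% Hodgkin-Huxley-type + 27% Markov-model nodal sodium
// conductance. Fixed-step integration at dt = 1e-3 ms: implicit Euler for
// the Markov occupancy block (unconditionally stable, conserves total
// probability because the generator rows sum to zero), semi-implicit
// (linearized backward) Euler for the gates and the two membrane
// potentials.
//
// The implicit Markov step solves p' (I - dt Q(V)) = p. Because V is
// essentially constant during long conditioning stretches, the LU
// factorization of (I - dt Q)^T is cached and only recomputed when the
// nodal potential has moved by more than 1e-6 mV (the resulting rate
// error is far below the integration error of the scheme itself).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// in-place LU with partial pivoting; A row-major n x n
static void lu_factor(std::vector<double> &A, std::vector<int> &piv, int n) {
  for (int col = 0; col < n; ++col) {
    int p = col;
    double amax = std::fabs(A[col * n + col]);
    for (int r = col + 1; r < n; ++r) {
      double v = std::fabs(A[r * n + col]);
      if (v > amax) { amax = v; p = r; }
    }
    piv[col] = p;
    if (p != col)
      for (int c = 0; c < n; ++c) std::swap(A[col * n + c], A[p * n + c]);
    double d = A[col * n + col];
    for (int r = col + 1; r < n; ++r) {
      double f = A[r * n + col] / d;
      A[r * n + col] = f;
      if (f == 0.0) continue;
      for (int c = col + 1; c < n; ++c) A[r * n + c] -= f * A[col * n + c];
    }
  }
}

static void lu_solve(const std::vector<double> &A, const std::vector<int> &piv,
                     std::vector<double> &b, int n) {
  for (int col = 0; col < n; ++col) {
    if (piv[col] != col) std::swap(b[col], b[piv[col]]);
    for (int r = col + 1; r < n; ++r) b[r] -= A[r * n + col] * b[col];
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int c = r + 1; c < n; ++c) s -= A[r * n + c] * b[c];
    b[r] = s / A[r * n + r];
  }
}

// [[Rcpp::export]]
List axon_run_cpp(NumericVector state0, NumericVector stim, double dt,
                  List pars, NumericMatrix gatepars, IntegerMatrix edges,
                  NumericMatrix ratepars, IntegerVector conducting,
                  double gate_tfac, int record_every) {
  const double cn = pars["cn"], ci = pars["ci"];
  const double gnaf = pars["gnaf"], gmk = pars["gmk"], gnap = pars["gnap"];
  const double gksn = pars["gksn"], gkfn = pars["gkfn"], gln = pars["gln"];
  const double gkfi = pars["gkfi"], gh = pars["gh"], gli = pars["gli"];
  const double gbb = pars["gbb"];
  const double ena = pars["ena"], ek = pars["ek"], eh = pars["eh"];
  const double elk = pars["elk"], ipump = pars["ipump"];
  NumericVector emult = pars["emult"];

  const int ngate = gatepars.nrow();          // m h p s nn ni q
  const int nedge = edges.nrow();
  int nstate = 0;
  for (int e = 0; e < nedge; ++e) {
    if (edges(e, 0) > nstate) nstate = edges(e, 0);
    if (edges(e, 1) > nstate) nstate = edges(e, 1);
  }
  nstate += 1;

  const int nsteps = stim.size();
  double vn = state0[0], vi = state0[1];
  std::vector<double> gate(ngate);
  for (int g = 0; g < ngate; ++g) gate[g] = state0[2 + g];
  std::vector<double> p(nstate);
  for (int s = 0; s < nstate; ++s) p[s] = state0[2 + ngate + s];

  const int nrec = nsteps / record_every + 1;
  NumericVector vrec(nrec), virec(nrec), trec(nrec);
  int ir = 0;
  double vn_max = vn;

  std::vector<double> A(nstate * nstate), b(nstate), Q(nstate * nstate);
  std::vector<int> piv(nstate);
  double v_lu = 1e300;                        // vn of the cached LU
  // cached gate targets
  std::vector<double> xinf(ngate), taug(ngate), vg(ngate, 1e300);

  for (int k = 0; k < nsteps; ++k) {
    // --- Markov block
    if (std::fabs(vn - v_lu) > 1e-6) {
      std::fill(Q.begin(), Q.end(), 0.0);
      for (int e = 0; e < nedge; ++e) {
        int from = edges(e, 0), to = edges(e, 1), ri = edges(e, 2);
        double rate = emult[e] * ratepars(ri, 0) *
                      std::exp(ratepars(ri, 1) * vn);
        Q[from * nstate + to] += rate;
        Q[from * nstate + from] -= rate;
      }
      for (int r = 0; r < nstate; ++r)
        for (int c = 0; c < nstate; ++c)
          A[r * nstate + c] = (r == c ? 1.0 : 0.0) - dt * Q[c * nstate + r];
      lu_factor(A, piv, nstate);
      v_lu = vn;
    }
    for (int s = 0; s < nstate; ++s) b[s] = p[s];
    lu_solve(A, piv, b, nstate);
    double psum = 0.0;
    for (int s = 0; s < nstate; ++s) psum += b[s];
    double po = 0.0;
    for (int s = 0; s < nstate; ++s) p[s] = b[s] / psum;
    for (int c2 = 0; c2 < conducting.size(); ++c2) po += p[conducting[c2]];

    // --- gates: x' = (x + dt xinf/tau) / (1 + dt/tau)
    for (int g = 0; g < ngate; ++g) {
      double v = (g >= 5) ? vi : vn;          // gates 5 (ni), 6 (q) internodal
      if (std::fabs(v - vg[g]) > 1e-9) {
        xinf[g] = 1.0 / (1.0 + std::exp((gatepars(g, 0) - v) / gatepars(g, 1)));
        taug[g] = (gatepars(g, 2) / std::cosh((v - gatepars(g, 3)) / gatepars(g, 4))
                   + gatepars(g, 5)) / gate_tfac;
        vg[g] = v;
      }
      gate[g] = (gate[g] + dt * xinf[g] / taug[g]) / (1.0 + dt / taug[g]);
    }
    const double m = gate[0], h = gate[1], pp = gate[2], s = gate[3];
    const double nn = gate[4], ni = gate[5], q = gate[6];

    // --- voltages: semi-implicit 2x2 solve
    double gm3h = gnaf * m * m * m * h;
    double gmk_po = gmk * po;
    double gp = gnap * pp;
    double gnn = gkfn * nn * nn * nn * nn;
    double gni = gkfi * ni * ni * ni * ni;
    double Gn = gm3h + gmk_po + gp + gksn * s + gnn + gln;
    double Sn = (gm3h + gmk_po + gp) * ena + (gksn * s + gnn) * ek +
                gln * elk - ipump + stim[k];
    double Gi = gni + gh * q + gli;
    double Si = gni * ek + gh * q * eh + gli * elk;

    double a11 = cn / dt + Gn + gbb, a12 = -gbb;
    double a21 = -gbb, a22 = ci / dt + Gi + gbb;
    double b1 = cn / dt * vn + Sn, b2 = ci / dt * vi + Si;
    double det = a11 * a22 - a12 * a21;
    double vn_new = (b1 * a22 - a12 * b2) / det;
    double vi_new = (a11 * b2 - b1 * a21) / det;
    vn = vn_new; vi = vi_new;
    if (vn > vn_max) vn_max = vn;
    if (k % record_every == 0) {
      vrec[ir] = vn; virec[ir] = vi; trec[ir] = (k + 1) * dt; ++ir;
    }
  }

  NumericVector stend(2 + ngate + nstate);
  stend[0] = vn; stend[1] = vi;
  for (int g = 0; g < ngate; ++g) stend[2 + g] = gate[g];
  for (int s = 0; s < nstate; ++s) stend[2 + ngate + s] = p[s];

  return List::create(_["v_node"] = vrec[Range(0, ir - 1)],
                      _["v_internode"] = virec[Range(0, ir - 1)],
                      _["time"] = trec[Range(0, ir - 1)],
                      _["state"] = stend,
                      _["vn_max"] = vn_max);
}
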