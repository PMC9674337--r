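// Branched-cable compartmental solver.
//
// Fixed-step implicit Euler on the tree (Hines ordering: parent index <
// child index, single backward elimination + forward substitution per
// step), Rush-Larsen exponential updates for HH-style gating variables,
// and an exact two-state recursion for alpha-conductance synapses.
//
// Units: mV, ms, uS, nF, nA (so g*V = nA and C*dV/dt = nA).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double sigm(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

// Channel gating descriptors ---------------------------------------------
// Densities arrive as an n x 7 matrix: na, kdr, hcn, kd, km, cat, kca.

struct Gates {
  // per compartment: na m,h; kdr n; hcn q; kd a,b; km u; cat mt,ht
  std::vector<double> m, h, n, q, a, b, u, mt, ht, ca;
};

// [[Rcpp::export]]
List cable_sim_cpp(IntegerVector parent, NumericVector length_um,
                   NumericVector diam_um, NumericVector ra_ohm_cm,
                   NumericVector ra_scale, NumericVector cm_uf_cm2,
                   NumericVector g_pas, NumericVector e_pas,
                   NumericMatrix dens, NumericVector revs,
                   IntegerVector ev_step, IntegerVector ev_comp,
                   NumericVector ev_w_us, IntegerVector ev_type,
                   double tau_e, double e_e, double tau_i, double e_i,
                   int nstep, double dt, double v_init,
                   IntegerVector record_idx, int record_every,
                   int spike_comp, double spike_thresh, double refrac_ms,
                   int inj_comp, double inj_na,
                   int inj_start, int inj_end,
                   bool clamp, double clamp_mv, NumericVector kin) {
  const int n = parent.size();
  const double ena = revs[0], ek = revs[1], eh = revs[2], eca = revs[3];
  // adjustable spike-channel kinetics: Na m/h midpoints+slopes, KDR midpoint
  const double namvh = kin[0], namk = kin[1], nahvh = kin[2],
      kdrvh = kin[3];

  // geometry -> capacitance, membrane conductance, axial conductance
  std::vector<double> cap(n), gpas(n), gax(n, 0.0); // gax: link to parent
  std::vector<double> area(n);
  for (int i = 0; i < n; ++i) {
    area[i] = M_PI * diam_um[i] * 1e-4 * length_um[i] * 1e-4; // cm^2
    cap[i] = cm_uf_cm2[i] * area[i] * 1e3;                    // nF
    gpas[i] = g_pas[i] * area[i] * 1e3;                       // uS
  }
  for (int i = 0; i < n; ++i) {
    int p = parent[i];
    if (p < 0) continue;
    double r_half_i = ra_ohm_cm[i] * (length_um[i] * 1e-4 / 2.0) /
      (M_PI * std::pow(diam_um[i] * 1e-4 / 2.0, 2.0));
    double r_half_p = ra_ohm_cm[p] * (length_um[p] * 1e-4 / 2.0) /
      (M_PI * std::pow(diam_um[p] * 1e-4 / 2.0, 2.0));
    double r = (r_half_i + r_half_p) * ra_scale[i]; // Ohm, scaled link
    gax[i] = 1e6 / r;                               // uS
  }

  // max conductances in uS
  std::vector<double> gna(n), gkdr(n), ghcn(n), gkd(n), gkm(n), gcat(n),
      gkca(n);
  for (int i = 0; i < n; ++i) {
    gna[i] = dens(i, 0) * area[i] * 1e3;
    gkdr[i] = dens(i, 1) * area[i] * 1e3;
    ghcn[i] = dens(i, 2) * area[i] * 1e3;
    gkd[i] = dens(i, 3) * area[i] * 1e3;
    gkm[i] = dens(i, 4) * area[i] * 1e3;
    gcat[i] = dens(i, 5) * area[i] * 1e3;
    gkca[i] = dens(i, 6) * area[i] * 1e3;
  }

  // state
  std::vector<double> v(n, v_init);
  Gates g;
  g.m.assign(n, 0); g.h.assign(n, 1); g.n.assign(n, 0); g.q.assign(n, 0);
  g.a.assign(n, 0); g.b.assign(n, 1); g.u.assign(n, 0);
  g.mt.assign(n, 0); g.ht.assign(n, 1); g.ca.assign(n, 0);
  for (int i = 0; i < n; ++i) { // gates at steady state for v_init
    double vv = v[i];
    g.m[i] = sigm(vv, namvh, namk);
    g.h[i] = sigm(vv, nahvh, -6.0);
    g.n[i] = sigm(vv, kdrvh, 9.0);
    g.q[i] = sigm(vv, -77.0, -9.0);
    g.a[i] = sigm(vv, -55.0, 9.0);
    g.b[i] = sigm(vv, -65.0, -6.0);
    g.u[i] = sigm(vv, -40.0, 9.0);
    g.mt[i] = sigm(vv, -52.0, 5.0);
    g.ht[i] = sigm(vv, -72.0, -5.0);
  }

  // synapses: two-state alpha recursion per compartment and class,
  // advanced in half steps so conductances are taken at the midpoint
  // of each voltage step (staggered, second-order coupling)
  std::vector<double> xe(n, 0), ge(n, 0), xi(n, 0), gi(n, 0);
  const double de = std::exp(-0.5 * dt / tau_e), re = 0.5 * dt / tau_e;
  const double di = std::exp(-0.5 * dt / tau_i), ri = 0.5 * dt / tau_i;

  // Hines factorization workspaces
  std::vector<double> diag(n), rhs(n);

  const int nrec = record_idx.size();
  const int nrec_steps = nstep / record_every + 1;
  NumericMatrix vm(nrec_steps, nrec);
  NumericVector t_rec(nrec_steps);
  std::vector<double> spikes;
  double last_spike = -1e9, v_prev_spk = v_init;
  double q_exc = 0.0, q_inh = 0.0; // pC accumulators

  int ev = 0;
  const int nev = ev_step.size();
  int rec_row = 0;

  for (int step = 0; step <= nstep; ++step) {
    double t_ms = step * dt;
    // record
    if (step % record_every == 0 && rec_row < nrec_steps) {
      for (int k = 0; k < nrec; ++k) vm(rec_row, k) = v[record_idx[k]];
      t_rec[rec_row] = t_ms;
      ++rec_row;
    }
    if (step == nstep) break;

    // deliver events scheduled for this step
    while (ev < nev && ev_step[ev] == step) {
      int c = ev_comp[ev];
      if (ev_type[ev] == 0) xe[c] += ev_w_us[ev] * std::exp(1.0);
      else xi[c] += ev_w_us[ev] * std::exp(1.0);
      ++ev;
    }

    // advance synapses to the step midpoint (exact half-step update),
    // accumulate charge with the midpoint conductance
    for (int i = 0; i < n; ++i) {
      ge[i] = (ge[i] + re * xe[i]) * de;
      xe[i] *= de;
      gi[i] = (gi[i] + ri * xi[i]) * di;
      xi[i] *= di;
      if (ge[i] > 0) q_exc += ge[i] * (e_e - v[i]) * dt; // uS*mV*ms = pC
      if (gi[i] > 0) q_inh += gi[i] * (e_i - v[i]) * dt;
    }

    // gating update (Rush-Larsen with V at step start)
    for (int i = 0; i < n; ++i) {
      double vv = v[i];
      if (gna[i] > 0) {
        double minf = sigm(vv, namvh, namk), taum = 0.05;
        double hinf = sigm(vv, nahvh, -6.0);
        double tauh = 0.2 + 2.5 / std::cosh((vv - nahvh) / 12.0);
        g.m[i] += (minf - g.m[i]) * (1 - std::exp(-dt / taum));
        g.h[i] += (hinf - g.h[i]) * (1 - std::exp(-dt / tauh));
      }
      if (gkdr[i] > 0) {
        double ninf = sigm(vv, kdrvh, 9.0);
        double taun = 0.5 + 3.0 / std::cosh((vv - kdrvh) / 15.0);
        g.n[i] += (ninf - g.n[i]) * (1 - std::exp(-dt / taun));
      }
      if (ghcn[i] > 0) {
        double qinf = sigm(vv, -77.0, -9.0);
        g.q[i] += (qinf - g.q[i]) * (1 - std::exp(-dt / 150.0));
      }
      if (gkd[i] > 0) {
        double ainf = sigm(vv, -55.0, 9.0), binf = sigm(vv, -65.0, -6.0);
        g.a[i] += (ainf - g.a[i]) * (1 - std::exp(-dt / 2.0));
        g.b[i] += (binf - g.b[i]) * (1 - std::exp(-dt / 150.0));
      }
      if (gkm[i] > 0) {
        double uinf = sigm(vv, -40.0, 9.0);
        g.u[i] += (uinf - g.u[i]) * (1 - std::exp(-dt / 80.0));
      }
      if (gcat[i] > 0) {
        double mtinf = sigm(vv, -52.0, 5.0), htinf = sigm(vv, -72.0, -5.0);
        g.mt[i] += (mtinf - g.mt[i]) * (1 - std::exp(-dt / 3.0));
        g.ht[i] += (htinf - g.ht[i]) * (1 - std::exp(-dt / 40.0));
      }
      if (gkca[i] > 0) {
        // Ca pool driven by the T-type current (arbitrary concentration
        // units; decay 100 ms)
        double ica = (gcat[i] > 0)
          ? gcat[i] * g.mt[i] * g.mt[i] * g.ht[i] * (vv - eca)
          : 0.0; // nA (negative inward)
        double ca_in = std::max(-ica, 0.0) / std::max(area[i] * 1e3, 1e-12);
        g.ca[i] += dt * (0.02 * ca_in - g.ca[i] / 100.0);
      }
    }

    if (clamp) {
      for (int i = 0; i < n; ++i) v[i] = clamp_mv;
      // complete the synapse half-step
      for (int i = 0; i < n; ++i) {
        ge[i] = (ge[i] + re * xe[i]) * de; xe[i] *= de;
        gi[i] = (gi[i] + ri * xi[i]) * di; xi[i] *= di;
      }
      continue;
    }

    // assemble diag/rhs (Crank-Nicolson: half the membrane and axial
    // operator on each side, conductances at the step midpoint)
    for (int i = 0; i < n; ++i) {
      double vv = v[i];
      double G = gpas[i], B = gpas[i] * e_pas[i];
      if (gna[i] > 0) {
        double gg = gna[i] * g.m[i] * g.m[i] * g.m[i] * g.h[i];
        G += gg; B += gg * ena;
      }
      if (gkdr[i] > 0) {
        double nn = g.n[i] * g.n[i]; nn *= nn;
        double gg = gkdr[i] * nn;
        G += gg; B += gg * ek;
      }
      if (ghcn[i] > 0) { double gg = ghcn[i] * g.q[i]; G += gg; B += gg * eh; }
      if (gkd[i] > 0) {
        double gg = gkd[i] * g.a[i] * g.a[i] * g.a[i] * g.b[i];
        G += gg; B += gg * ek;
      }
      if (gkm[i] > 0) { double gg = gkm[i] * g.u[i]; G += gg; B += gg * ek; }
      if (gcat[i] > 0) {
        double gg = gcat[i] * g.mt[i] * g.mt[i] * g.ht[i];
        G += gg; B += gg * eca;
      }
      if (gkca[i] > 0) {
        double z = g.ca[i] * g.ca[i] / (g.ca[i] * g.ca[i] + 0.25);
        double gg = gkca[i] * z;
        G += gg; B += gg * ek;
      }
      if (ge[i] > 0) { G += ge[i]; B += ge[i] * e_e; }
      if (gi[i] > 0) { G += gi[i]; B += gi[i] * e_i; }
      if (i == inj_comp && step >= inj_start && step < inj_end) B += inj_na;
      diag[i] = cap[i] / dt + 0.5 * G;
      rhs[i] = cap[i] / dt * vv - 0.5 * G * vv + B;
    }
    // axial couplings: half on each side of the step
    for (int i = 0; i < n; ++i) {
      int p = parent[i];
      if (p < 0) continue;
      diag[i] += 0.5 * gax[i];
      diag[p] += 0.5 * gax[i];
      double iax = 0.5 * gax[i] * (v[i] - v[p]);
      rhs[i] -= iax;
      rhs[p] += iax;
    }
    // backward elimination (children before parents; parent[i] < i)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double a = 0.5 * gax[i];
      double f = a / diag[i];
      diag[p] -= a * f;
      rhs[p] += rhs[i] * f;
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      v[i] = (rhs[i] + 0.5 * gax[i] * v[parent[i]]) / diag[i];
    }
    // complete the synapse half-step to the end of the interval
    for (int i = 0; i < n; ++i) {
      ge[i] = (ge[i] + re * xe[i]) * de; xe[i] *= de;
      gi[i] = (gi[i] + ri * xi[i]) * di; xi[i] *= di;
    }
    if (!std::isfinite(v[0])) {
      stop("numerical failure: membrane potential diverged at t = %f ms",
           t_ms);
    }

    // spike detection (upward crossing, refractory de-duplication)
    if (spike_comp >= 0) {
      double vs = v[spike_comp];
      if (v_prev_spk < spike_thresh && vs >= spike_thresh &&
          (t_ms - last_spike) > refrac_ms) {
        spikes.push_back(t_ms + dt);
        last_spike = t_ms + dt;
      }
      v_prev_spk = vs;
    }
  }

  return List::create(
    _["vm"] = vm, _["t_ms"] = t_rec,
    _["spike_t_ms"] = NumericVector(spikes.begin(), spikes.end()),
    _["exc_charge_nC"] = q_exc * 1e-3,
    _["inh_charge_nC"] = q_inh * 1e-3);
}

// 3x3 median filter with edge replication ---------------------------------

// [[Rcpp::export]]
NumericMatrix median3_cpp(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double w[9];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -1; di <= 1; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          w[k++] = x(ii, jj);
        }
      }
      std::nth_element(w, w + 4, w + 9);
      out(i, j) = w[4];
    }
  }
  return out;
}
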