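// Mass-conservative 1-D Richards solver (mixed form, modified Picard),
// cell-centered grid, depth positive downward, heads in cm, time in days.
// Upper boundary: atmospheric flux demand with automatic switching to
// ponded-head (h = 0) or dry-surface (h = h_dry) Dirichlet control.
// Lower boundary: free drainage (unit gradient, q = K(h_bottom)).
// Root water uptake: Feddes pressure-head reduction, evaluated per substep.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Soil {
  int N;
  double dz;
  std::vector<double> tr, ts, al, vn, vm, ks;
};

inline double se_of_h(const Soil& s, int i, double h) {
  if (h >= 0.0) return 1.0;
  double ah = s.al[i] * (-h);
  return std::pow(1.0 + std::pow(ah, s.vn[i]), -s.vm[i]);
}

inline double theta_of_h(const Soil& s, int i, double h) {
  return s.tr[i] + (s.ts[i] - s.tr[i]) * se_of_h(s, i, h);
}

// specific moisture capacity C = d theta / d h
inline double cap_of_h(const Soil& s, int i, double h) {
  if (h >= 0.0) return 1e-12;
  double a = s.al[i], n = s.vn[i], m = s.vm[i];
  double ah = a * (-h);
  double ahn = std::pow(ah, n);
  double c = (s.ts[i] - s.tr[i]) * m * n * a * std::pow(ah, n - 1.0) *
             std::pow(1.0 + ahn, -m - 1.0);
  return std::max(c, 1e-12);
}

inline double k_of_se(const Soil& s, int i, double se) {
  se = std::min(1.0, std::max(1e-12, se));
  double m = s.vm[i];
  double t = 1.0 - std::pow(1.0 - std::pow(se, 1.0 / m), m);
  return s.ks[i] * std::sqrt(se) * t * t;
}

inline double k_of_h(const Soil& s, int i, double h) {
  return k_of_se(s, i, se_of_h(s, i, h));
}

inline double feddes_alpha(double h, double h1, double h2, double h3,
                           double h4) {
  if (h >= h1 || h <= h4) return 0.0;
  if (h >= h2) return (h1 - h) / (h1 - h2);
  if (h >= h3) return 1.0;
  return (h - h4) / (h3 - h4);
}

void thomas(const std::vector<double>& a, std::vector<double>& b,
            const std::vector<double>& c, std::vector<double>& d,
            std::vector<double>& x) {
  int n = (int)b.size();
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  x[n - 1] = d[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = (d[i] - c[i] * x[i + 1]) / b[i];
}

// Solve one substep by modified Picard.  top_mode: 0 flux, 1 ponded h=0,
// 2 dry surface h=h_dry.  Returns true on convergence; fills h_new, the
// realized surface flux q_top (positive downward) and bottom flux q_bot.
bool picard_substep(const Soil& s, const std::vector<double>& h_old,
                    const std::vector<double>& sink, double dt, int top_mode,
                    double q_demand, double h_surf, int max_iter,
                    double tol_theta, double tol_h,
                    std::vector<double>& h_new, double& q_top, double& q_bot) {
  int N = s.N;
  double dz = s.dz;
  std::vector<double> th_old(N), h(h_old), kk(N), cc(N), tt(N);
  std::vector<double> A(N), B(N), C(N), D(N), hx(N), kint(N + 1, 0.0);
  for (int i = 0; i < N; ++i) th_old[i] = theta_of_h(s, i, h_old[i]);

  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      kk[i] = k_of_h(s, i, h[i]);
      cc[i] = cap_of_h(s, i, h[i]);
      tt[i] = theta_of_h(s, i, h[i]);
    }
    for (int i = 1; i < N; ++i) kint[i] = 0.5 * (kk[i - 1] + kk[i]);
    double k_surf = 0.0;
    if (top_mode != 0) k_surf = 0.5 * (k_of_h(s, 0, h_surf) + kk[0]);
    double k_bot = kk[N - 1];  // free drainage, lagged

    for (int i = 0; i < N; ++i) {
      double diag = cc[i] * dz / dt;
      double rhs = diag * h[i] - (tt[i] - th_old[i]) * dz / dt - sink[i];
      double au = 0.0, cl = 0.0;
      if (i > 0) {
        au = -kint[i] / dz;
        diag += kint[i] / dz;
        rhs += kint[i];  // gravity inflow through the upper interface
      } else if (top_mode == 0) {
        rhs += q_demand;
      } else {
        diag += k_surf / (dz / 2.0);
        rhs += k_surf * (h_surf / (dz / 2.0) + 1.0);
      }
      if (i < N - 1) {
        cl = -kint[i + 1] / dz;
        diag += kint[i + 1] / dz;
        rhs -= kint[i + 1];  // gravity outflow through the lower interface
      } else {
        rhs -= k_bot;
      }
      A[i] = au; B[i] = diag; C[i] = cl; D[i] = rhs;
    }
    thomas(A, B, C, D, hx);
    // dual convergence test (per node): water-content change while
    // unsaturated, pressure-head change once near saturation
    bool pass = true;
    for (int i = 0; i < N; ++i) {
      double hn = std::max(hx[i], -1e7);
      if (h[i] < 0.0 && hn < 0.0) {
        if (std::fabs(theta_of_h(s, i, hn) - tt[i]) > tol_theta) pass = false;
      } else {
        if (std::fabs(hn - h[i]) > tol_h) pass = false;
      }
      h[i] = hn;
    }
    if (pass && it > 0) { converged = true; break; }
  }
  if (!converged) return false;

  // realized boundary fluxes with the converged (lagged) conductivities
  if (top_mode == 0) q_top = q_demand;
  else {
    double k_surf = 0.5 * (k_of_h(s, 0, h_surf) + k_of_h(s, 0, h[0]));
    q_top = k_surf * ((h_surf - h[0]) / (s.dz / 2.0) + 1.0);
  }
  q_bot = k_of_h(s, N - 1, h[N - 1]);
  h_new = h;
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".richards_day_cpp")]]
List richards_day_cpp(NumericVector h0, NumericVector theta_r,
                      NumericVector theta_s, NumericVector alpha,
                      NumericVector vgn, NumericVector ks, double dz,
                      double rain, double ep, double tp,
                      NumericVector root_frac, NumericVector feddes,
                      Nullable<NumericVector> sink_fixed = R_NilValue,
                      double total_time = 1.0, double dt_init = 0.05,
                      double dt_min = 1e-4, double dt_max = 0.25,
                      int max_iter = 40, double tol = 1e-4,
                      double h_dry = -1e5, int max_substeps = 4000) {
  int N = h0.size();
  Soil s;
  s.N = N; s.dz = dz;
  s.tr.assign(theta_r.begin(), theta_r.end());
  s.ts.assign(theta_s.begin(), theta_s.end());
  s.al.assign(alpha.begin(), alpha.end());
  s.vn.assign(vgn.begin(), vgn.end());
  s.ks.assign(ks.begin(), ks.end());
  s.vm.resize(N);
  for (int i = 0; i < N; ++i) s.vm[i] = 1.0 - 1.0 / s.vn[i];

  bool use_fixed = sink_fixed.isNotNull();
  std::vector<double> sfix;
  if (use_fixed) {
    NumericVector sf(sink_fixed);
    sfix.assign(sf.begin(), sf.end());  // cm d-1 extracted per node
  }
  double f1 = feddes[0], f2 = feddes[1], f3 = feddes[2], f4 = feddes[3];

  std::vector<double> h(h0.begin(), h0.end()), h_new(N), sink(N, 0.0);
  std::vector<double> q_int_acc(N + 1, 0.0), sink_acc(N, 0.0);
  double th0_sum = 0.0;
  for (int i = 0; i < N; ++i) th0_sum += theta_of_h(s, i, h[i]) * dz;

  double t = 0.0, dt = std::min(dt_init, total_time);
  double ea_cum = 0.0, ta_cum = 0.0, runoff_cum = 0.0, infil_cum = 0.0,
         drain_cum = 0.0;
  int n_sub = 0;
  double q_demand_full = rain - ep;  // cm d-1, positive downward

  while (t < total_time - 1e-12) {
    dt = std::min(dt, total_time - t);
    // sink for this substep from current heads
    double ta_rate = 0.0;
    for (int i = 0; i < N; ++i) {
      double si;
      if (use_fixed) si = sfix[i];
      else si = feddes_alpha(h[i], f1, f2, f3, f4) * root_frac[i] * tp;
      sink[i] = si;
      ta_rate += si;
    }
    double q_top = 0.0, q_bot = 0.0;
    bool ok = picard_substep(s, h, sink, dt, 0, q_demand_full, 0.0, max_iter,
                             tol, 0.05, h_new, q_top, q_bot);
    int mode = 0;
    if (ok && q_demand_full > 0.0 && h_new[0] > 0.0) {
      ok = picard_substep(s, h, sink, dt, 1, q_demand_full, 0.0, max_iter,
                          tol, 0.05, h_new, q_top, q_bot);
      mode = 1;
      if (ok && q_top > q_demand_full) {  // surface not actually limiting
        ok = picard_substep(s, h, sink, dt, 0, q_demand_full, 0.0, max_iter,
                            tol, 0.05, h_new, q_top, q_bot);
        mode = 0;
      }
    } else if (ok && q_demand_full < 0.0 && h_new[0] < h_dry) {
      ok = picard_substep(s, h, sink, dt, 2, q_demand_full, h_dry, max_iter,
                          tol, 0.05, h_new, q_top, q_bot);
      mode = 2;
      if (ok && q_top < q_demand_full) {  // exfiltration exceeds demand
        ok = picard_substep(s, h, sink, dt, 0, q_demand_full, 0.0, max_iter,
                            tol, 0.05, h_new, q_top, q_bot);
        mode = 0;
      }
    }
    double err_sub = 0.0;
    if (ok) {
      // column closure error of this substep (cm) and per-cell water move
      double dstor = 0.0, dth_max = 0.0;
      for (int i = 0; i < N; ++i) {
        double dth = theta_of_h(s, i, h_new[i]) - theta_of_h(s, i, h[i]);
        dstor += dth * dz;
        if (std::fabs(dth) > dth_max) dth_max = std::fabs(dth);
      }
      err_sub = dstor - (q_top - q_bot - ta_rate) * dt;
      if (dt > dt_min * 1.01 &&
          (dth_max > 0.05 || std::fabs(err_sub) > 2e-4)) {
        ok = false;  // refine: front under-resolved for this step size
      }
    }
    if (!ok) {
      if (dt <= dt_min * 1.01)
        stop("richards: solver failed to converge at t = %f d (dt = dt_min)",
             t);
      dt = std::max(dt * 0.5, dt_min);
      continue;
    }

    // accounting (cm over the substep)
    if (mode == 0) {
      infil_cum += q_top * dt;
      ea_cum += ep * dt;
    } else if (mode == 1) {
      infil_cum += q_top * dt;
      ea_cum += ep * dt;
      runoff_cum += (q_demand_full - q_top) * dt;
    } else {
      infil_cum += q_top * dt;
      ea_cum += (rain - q_top) * dt;
    }
    drain_cum += q_bot * dt;
    ta_cum += ta_rate * dt;

    // time-averaged interface fluxes for solute transport
    q_int_acc[0] += q_top * dt;
    for (int i = 1; i < N; ++i) {
      double kint = 0.5 * (k_of_h(s, i - 1, h_new[i - 1]) +
                           k_of_h(s, i, h_new[i]));
      q_int_acc[i] += kint * ((h_new[i - 1] - h_new[i]) / dz + 1.0) * dt;
    }
    q_int_acc[N] += q_bot * dt;
    for (int i = 0; i < N; ++i) sink_acc[i] += sink[i] * dt;

    h = h_new;
    t += dt;
    ++n_sub;
    if (n_sub > max_substeps)
      stop("richards: substep budget exhausted at t = %f d", t);
    dt = std::min(dt * 1.3, dt_max);
  }

  NumericVector h_out(N), theta_out(N), qint(N + 1), sink_out(N);
  double th1_sum = 0.0;
  for (int i = 0; i < N; ++i) {
    h_out[i] = h[i];
    theta_out[i] = theta_of_h(s, i, h[i]);
    th1_sum += theta_out[i] * dz;
    sink_out[i] = sink_acc[i] / total_time;
  }
  for (int i = 0; i <= N; ++i) qint[i] = q_int_acc[i] / total_time;

  double storage_change = th1_sum - th0_sum;  // cm
  double balance_error =
      infil_cum - ta_cum - drain_cum - storage_change;  // cm

  return List::create(
      _["h"] = h_out, _["theta"] = theta_out,
      _["infiltration"] = infil_cum, _["runoff"] = runoff_cum,
      _["ea"] = ea_cum, _["ta"] = ta_cum, _["drainage"] = drain_cum,
      _["storage_change"] = storage_change,
      _["balance_error"] = balance_error, _["q_int"] = qint,
      _["sink"] = sink_out, _["n_substeps"] = n_sub);
}

// Multi-day water-only run used by the hydraulic calibration: daily forcing
// vectors, returns water contents at requested nodes at the end of each day.
// [[Rcpp::export(name = ".richards_run_cpp")]]
List richards_run_cpp(NumericVector h0, NumericVector theta_r,
                      NumericVector theta_s, NumericVector alpha,
                      NumericVector vgn, NumericVector ks, double dz,
                      NumericVector rain, NumericVector ep, NumericVector tp,
                      NumericMatrix root_frac, NumericVector feddes,
                      IntegerVector out_nodes, double dt_init = 0.05,
                      double dt_min = 1e-4, double dt_max = 0.25,
                      int max_iter = 40, double tol = 1e-4,
                      double h_dry = -1e5, int max_substeps = 4000) {
  int ndays = rain.size();
  int N = h0.size();
  NumericMatrix theta_out(out_nodes.size(), ndays);
  NumericVector ta_out(ndays), drain_out(ndays), bal_out(ndays);
  NumericVector h = clone(h0);
  for (int d = 0; d < ndays; ++d) {
    NumericVector rf = root_frac(_, d);
    List st = richards_day_cpp(h, theta_r, theta_s, alpha, vgn, ks, dz,
                               rain[d], ep[d], tp[d], rf, feddes, R_NilValue,
                               1.0, dt_init, dt_min, dt_max, max_iter, tol,
                               h_dry, max_substeps);
    h = st["h"];
    NumericVector th = st["theta"];
    for (int j = 0; j < out_nodes.size(); ++j)
      theta_out(j, d) = th[out_nodes[j] - 1];
    ta_out[d] = st["ta"];
    drain_out[d] = st["drainage"];
    bal_out[d] = st["balance_error"];
  }
  return List::create(_["theta"] = theta_out, _["ta"] = ta_out,
                      _["drainage"] = drain_out,
                      _["balance_error"] = bal_out, _["h"] = h);
}
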