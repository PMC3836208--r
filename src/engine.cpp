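// ODE engine for the niche-competition model.
//
// The model is expressed over *classes* of exchangeable species and niches:
// every member of a species class has the same per-member abundance and every
// niche of a niche class sees the same competitor field.  The full m x n
// system is the special case in which every class has exactly one member
// (Acol == Arow == A).  Collapsing exchangeable species makes the 2q-species
// screen systems 2- or 3-dimensional, which is what makes the exhaustive
// 3 x 41^3 parameter sweep tractable.
//
// Acol[i,j]: summed affinity of all members of species class i for ONE niche
//            of niche class j (enters the competition denominator).
// Arow[i,j]: summed affinity of ONE member of species class i over ALL niches
//            of niche class j (enters that member's resource intake).
//
// Integrator: Dormand-Prince 5(4) with the classic order-4 dense-output
// interpolant; states are examined on a fixed checkpoint grid where
// sub-threshold abundances are clamped to exactly 0 and the relative-change
// steady-state criterion is evaluated.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct ClassModel {
  int nS, nN;
  std::vector<double> Acol, Arow;  // nS x nN, column-major
  std::vector<double> p;           // supply of one niche of class j
  std::vector<double> v;           // efficiency per species class
  double tau;
};

// dc_i/dt = (c_i/tau) (1 - c_i/k_i) with k_i = v_i * c_i * S_i where
// S_i = sum_j Arow[i,j] p_j / D_j over niches with positive denominator,
// so c_i/k_i = 1/(v_i S_i) independently of c_i.
inline void rhs(const ClassModel& M, const double* c, double* dc,
                double* Dbuf) {
  for (int j = 0; j < M.nN; ++j) {
    double D = 0.0;
    const double* a = &M.Acol[(size_t)j * M.nS];
    for (int i = 0; i < M.nS; ++i) {
      const double ci = c[i] > 0.0 ? c[i] : 0.0;
      D += a[i] * ci;
    }
    Dbuf[j] = D;
  }
  for (int i = 0; i < M.nS; ++i) {
    double S = 0.0;
    for (int j = 0; j < M.nN; ++j) {
      if (Dbuf[j] > 0.0)
        S += M.Arow[i + (size_t)j * M.nS] * M.p[j] / Dbuf[j];
    }
    const double g = M.v[i] * S;
    dc[i] = (c[i] > 0.0 && g > 0.0) ? c[i] / M.tau * (1.0 - 1.0 / g) : 0.0;
  }
}

// Dormand-Prince coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double a71 = 35.0 / 384, a73 = 500.0 / 1113, a74 = 125.0 / 192,
             a75 = -2187.0 / 6784, a76 = 11.0 / 84;
// y5 - y4 (embedded error) weights
const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
             e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;
// dense-output weights
const double d1 = -12715105075.0 / 11282082432.0,
             d3 = 87487479700.0 / 32700410799.0,
             d4 = -10690763975.0 / 1880347072.0,
             d5 = 701980252875.0 / 199316789632.0,
             d6 = -1453857185.0 / 822651844.0,
             d7 = 69997945.0 / 29380423.0;

struct Stepper {
  const ClassModel* M;
  int n;
  std::vector<double> k1, k2, k3, k4, k5, k6, k7, ytmp, Dbuf;
  std::vector<double> r1, r2, r3, r4, r5;  // dense-output coefficients

  explicit Stepper(const ClassModel& model)
      : M(&model),
        n(model.nS),
        k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n), ytmp(n),
        Dbuf(model.nN), r1(n), r2(n), r3(n), r4(n), r5(n) {}

  void f(const double* y, double* dy) { rhs(*M, y, dy, Dbuf.data()); }

  // one trial step from (t, y) with slope k1 already evaluated; fills y_new,
  // k7 = f(y_new) and returns the scaled error norm
  double try_step(const double* y, double h, double rtol, double atol,
                  double* y_new) {
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    f(ytmp.data(), k2.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    f(ytmp.data(), k3.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    f(ytmp.data(), k4.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    f(ytmp.data(), k5.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    f(ytmp.data(), k6.data());
    for (int i = 0; i < n; ++i)
      y_new[i] = y[i] + h * (a71 * k1[i] + a73 * k3[i] + a74 * k4[i] +
                             a75 * k5[i] + a76 * k6[i]);
    f(y_new, k7.data());
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                             e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc =
          atol + rtol * std::max(std::fabs(y[i]), std::fabs(y_new[i]));
      const double q = ei / sc;
      err += q * q;
    }
    return std::sqrt(err / n);
  }

  void prepare_dense(const double* y, const double* y_new, double h) {
    for (int i = 0; i < n; ++i) {
      const double dy = y_new[i] - y[i];
      r1[i] = y[i];
      r2[i] = dy;
      r3[i] = h * k1[i] - dy;
      r4[i] = dy - h * k7[i] - r3[i];
      r5[i] = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                   d6 * k6[i] + d7 * k7[i]);
    }
  }

  void dense_eval(double theta, double* out) const {
    const double th1 = 1.0 - theta;
    for (int i = 0; i < n; ++i)
      out[i] = r1[i] +
               theta * (r2[i] + th1 * (r3[i] + theta * (r4[i] + th1 * r5[i])));
  }
};

struct Settings {
  double rel_change_tol, check_interval, t_max, rtol, atol, floor_;
  bool stop_at_convergence;
};

struct RunResult {
  std::vector<double> final_state;
  bool converged = false;
  double t_converged = NA_REAL;
  double t_end = 0.0;
  long n_steps = 0;
};

// clamp sub-floor (and negative) abundances to exactly 0; returns true if
// anything changed
inline bool clamp_state(std::vector<double>& y, double floor_) {
  bool changed = false;
  for (size_t i = 0; i < y.size(); ++i) {
    if (y[i] != 0.0 && y[i] < floor_) {
      y[i] = 0.0;
      changed = true;
    } else if (y[i] < 0.0) {  // floor_ == 0 case
      y[i] = 0.0;
      changed = true;
    }
  }
  return changed;
}

inline double rel_change(const std::vector<double>& now,
                         const std::vector<double>& prev, double floor_) {
  double m = 0.0;
  for (size_t i = 0; i < now.size(); ++i) {
    const double den = std::max(prev[i], floor_ > 0.0 ? floor_ : 1e-300);
    const double rc = std::fabs(now[i] - prev[i]) / den;
    if (rc > m) m = rc;
  }
  return m;
}

// Integrate one class system.  Events are proportional cell kills applied at
// times that must lie on the checkpoint grid; the recorded state at an event
// time is the pre-kill state (the jump shows up at the next checkpoint).
// If `traj_*` are non-null, the (clamped) state at every checkpoint is stored.
int run_model(const ClassModel& M, std::vector<double> y, const Settings& S,
              const std::vector<double>& ev_t, const std::vector<double>& ev_f,
              std::vector<double>* traj_t, std::vector<double>* traj_y,
              RunResult& out) {
  const int n = M.nS;
  const double ci = S.check_interval;
  const double tiny = 1e-9 * ci;
  Stepper st(M);

  clamp_state(y, S.floor_);
  if (traj_t) {
    traj_t->push_back(0.0);
    traj_y->insert(traj_y->end(), y.begin(), y.end());
  }
  std::vector<double> prev = y, y_new(n), y_cp(n);
  std::vector<double> yv(n);

  double t = 0.0;
  double h = std::min(1e-2, ci);
  long cp_k = 1;                 // index of next checkpoint
  size_t ev_i = 0;               // index of next pending event
  bool have_k1 = false;
  const double hmin = 1e-12;

  while (t < S.t_max - tiny) {
    if (!have_k1) {
      st.f(y.data(), st.k1.data());
      have_k1 = true;
    }
    // do not step across the next kill event
    double t_stop = S.t_max;
    if (ev_i < ev_t.size() && ev_t[ev_i] < t_stop) t_stop = ev_t[ev_i];
    if (h > t_stop - t) h = t_stop - t;
    if (h < hmin) h = hmin;

    // attempt / retry until accepted
    double err;
    for (;;) {
      err = st.try_step(y.data(), h, S.rtol, S.atol, y_new.data());
      ++out.n_steps;
      if (err <= 1.0 || h <= hmin) break;
      h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
      if (h < hmin) h = hmin;
    }
    const double t_new = t + h;
    st.prepare_dense(y.data(), y_new.data(), h);

    // next step size (clipped growth)
    double fac = err > 0.0 ? 0.9 * std::pow(err, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    double h_next = h * fac;

    // walk all checkpoints inside (t, t_new]
    bool restart = false;
    while (!restart) {
      const double tc = cp_k * ci;
      if (tc > t_new + tiny) break;
      if (std::fabs(tc - t_new) <= tiny) {
        std::copy(y_new.begin(), y_new.end(), y_cp.begin());
      } else {
        st.dense_eval((tc - t) / h, y_cp.data());
      }
      std::vector<double> yc(y_cp.begin(), y_cp.end());
      const bool clamped = clamp_state(yc, S.floor_);
      if (traj_t) {
        traj_t->push_back(tc);
        traj_y->insert(traj_y->end(), yc.begin(), yc.end());
      }
      const double rc = rel_change(yc, prev, S.floor_);
      if (rc < S.rel_change_tol && !out.converged) {
        out.converged = true;
        out.t_converged = tc;
        if (S.stop_at_convergence) {
          out.final_state = yc;
          out.t_end = tc;
          return 0;
        }
      }
      prev = yc;
      ++cp_k;

      bool fired = false;
      if (ev_i < ev_t.size() && std::fabs(ev_t[ev_i] - tc) <= tiny) {
        const double keep = 1.0 - ev_f[ev_i];
        for (int i = 0; i < n; ++i) yc[i] *= keep;
        clamp_state(yc, S.floor_);
        prev = yc;  // compare next checkpoint against the post-kill state
        ++ev_i;
        fired = true;
        // a perturbation invalidates any previously declared steady state
        out.converged = false;
        out.t_converged = NA_REAL;
      }
      if (fired || clamped) {
        // resume integration from the modified checkpoint state
        t = tc;
        y = yc;
        have_k1 = false;
        restart = true;
      }
    }
    if (!restart) {
      t = t_new;
      std::swap(y, y_new);
      std::copy(st.k7.begin(), st.k7.end(), st.k1.begin());  // FSAL
    }
    h = h_next;
    if (out.n_steps % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  out.final_state = y;
  clamp_state(out.final_state, S.floor_);
  out.t_end = t;
  return 0;
}

ClassModel model_from_r(NumericVector p, NumericVector v, double tau,
                        NumericMatrix Acol, NumericMatrix Arow) {
  ClassModel M;
  M.nS = Acol.nrow();
  M.nN = Acol.ncol();
  M.Acol.assign(Acol.begin(), Acol.end());
  M.Arow.assign(Arow.begin(), Arow.end());
  M.p.assign(p.begin(), p.end());
  M.v.assign(v.begin(), v.end());
  M.tau = tau;
  return M;
}

Settings settings_from_r(List s) {
  Settings S;
  S.rel_change_tol = as<double>(s["rel_change_tol"]);
  S.check_interval = as<double>(s["check_interval"]);
  S.t_max = as<double>(s["t_max"]);
  S.rtol = as<double>(s["rtol"]);
  S.atol = as<double>(s["atol"]);
  S.floor_ = as<double>(s["abundance_floor"]);
  S.stop_at_convergence = as<bool>(s["stop_at_convergence"]);
  return S;
}

}  // namespace

// [[Rcpp::export(name = ".engine_integrate")]]
List engine_integrate(NumericVector c0, NumericMatrix Acol,
                      NumericMatrix Arow, NumericVector p, NumericVector v,
                      double tau, List settings, NumericVector event_times,
                      NumericVector event_fractions, bool save_trajectory) {
  ClassModel M = model_from_r(p, v, tau, Acol, Arow);
  Settings S = settings_from_r(settings);
  std::vector<double> y(c0.begin(), c0.end());
  std::vector<double> ev_t(event_times.begin(), event_times.end());
  std::vector<double> ev_f(event_fractions.begin(), event_fractions.end());
  std::vector<double> traj_t, traj_y;
  RunResult res;
  run_model(M, y, S, ev_t, ev_f, save_trajectory ? &traj_t : nullptr,
            save_trajectory ? &traj_y : nullptr, res);

  List out = List::create(
      _["final"] = NumericVector(res.final_state.begin(),
                                 res.final_state.end()),
      _["converged"] = res.converged, _["t_converged"] = res.t_converged,
      _["t_end"] = res.t_end, _["n_steps"] = (double)res.n_steps);
  if (save_trajectory) {
    const int nt = (int)traj_t.size();
    NumericMatrix states(nt, M.nS);
    for (int r = 0; r < nt; ++r)
      for (int i = 0; i < M.nS; ++i)
        states(r, i) = traj_y[(size_t)r * M.nS + i];
    out["times"] = NumericVector(traj_t.begin(), traj_t.end());
    out["states"] = states;
  }
  return out;
}

namespace {

// class-reduced systems for the transformation-assay scenarios -------------

// monoclonal: species classes {healthy clone 1, preleukemic clone 1},
// niche classes {preferred niche (1), remaining n-1 niches}
ClassModel mono_model(double s_h, double u_h, double v_h, double s_p,
                      double u_p, double v_p, int n, double p_supply,
                      double tau) {
  ClassModel M;
  M.nS = 2;
  M.nN = 2;
  M.Acol = {s_h + u_h, s_p + u_p, u_h, u_p};
  M.Arow = {s_h + u_h, s_p + u_p, (n - 1.0) * u_h, (n - 1.0) * u_p};
  M.p = {p_supply, p_supply};
  M.v = {v_h, v_p};
  M.tau = tau;
  return M;
}

// polyclonal: species classes {healthy with seeded preleukemic sibling (n1),
// healthy without (n2), seeded preleukemic (n1)}, niche classes {niches
// preferred by seeded clones (n1), the rest (n2)}; n2 == 0 collapses to 2x1
ClassModel poly_model(double s_h, double u_h, double v_h, double s_p,
                      double u_p, double v_p, int q, int n_pre,
                      double p_supply, double tau) {
  ClassModel M;
  const double n1 = n_pre, n2 = q - n_pre;
  if (n_pre == q) {
    M.nS = 2;
    M.nN = 1;
    M.Acol = {s_h + n1 * u_h, s_p + n1 * u_p};
    M.Arow = {s_h + n1 * u_h, s_p + n1 * u_p};
    M.p = {p_supply};
    M.v = {v_h, v_p};
  } else {
    M.nS = 3;
    M.nN = 2;
    M.Acol = {s_h + n1 * u_h, n2 * u_h,            s_p + n1 * u_p,
              n1 * u_h,       s_h + n2 * u_h,      n1 * u_p};
    M.Arow = {s_h + n1 * u_h, n1 * u_h,            s_p + n1 * u_p,
              n2 * u_h,       s_h + n2 * u_h,      n2 * u_p};
    M.p = {p_supply, p_supply};
    M.v = {v_h, v_h, v_p};
  }
  M.tau = tau;
  return M;
}

}  // namespace

// Sweep of (s_fold, u_fold, v_fold) triples for one scenario; returns the
// steady-state totals and preleukemic fractions of the monoclonal and
// polyclonal runs.  poly_c0 holds the per-member initial abundances of the
// polyclonal species classes (length 3, ordered paired-healthy, unpaired-
// healthy, preleukemic; the middle entry is ignored when n_pre == q).
// [[Rcpp::export(name = ".engine_screen")]]
List engine_screen(NumericVector s_fold, NumericVector u_fold,
                   NumericVector v_fold, double s_h, double u_h, double v_h,
                   int q, int n_pre, int total_cells, double p_supply,
                   double tau, NumericVector poly_c0, List settings) {
  const int R = s_fold.size();
  Settings S = settings_from_r(settings);
  std::vector<double> no_ev;

  NumericVector mono_total(R), mono_frac(R), poly_total(R), poly_frac(R);
  LogicalVector mono_conv(R), poly_conv(R);
  NumericVector mono_tc(R), poly_tc(R);

  const double wh1 = n_pre, wh2 = q - n_pre, wpk = n_pre;

  for (int r = 0; r < R; ++r) {
    const double s_p = s_fold[r] * s_h;
    const double u_p = u_fold[r] * u_h;
    const double v_p = v_fold[r] * v_h;

    {  // monoclonal
      ClassModel M = mono_model(s_h, u_h, v_h, s_p, u_p, v_p, q, p_supply,
                                tau);
      std::vector<double> y = {(double)(total_cells - n_pre), (double)n_pre};
      RunResult res;
      run_model(M, y, S, no_ev, no_ev, nullptr, nullptr, res);
      const double tot = res.final_state[0] + res.final_state[1];
      mono_total[r] = tot;
      mono_frac[r] = tot > 0.0 ? res.final_state[1] / tot : 0.0;
      mono_conv[r] = res.converged;
      mono_tc[r] = res.t_converged;
    }
    {  // polyclonal
      ClassModel M = poly_model(s_h, u_h, v_h, s_p, u_p, v_p, q, n_pre,
                                p_supply, tau);
      std::vector<double> y;
      if (n_pre == q)
        y = {poly_c0[0], poly_c0[2]};
      else
        y = {poly_c0[0], poly_c0[1], poly_c0[2]};
      RunResult res;
      run_model(M, y, S, no_ev, no_ev, nullptr, nullptr, res);
      double tot, pk;
      if (n_pre == q) {
        tot = wh1 * res.final_state[0] + wpk * res.final_state[1];
        pk = wpk * res.final_state[1];
      } else {
        tot = wh1 * res.final_state[0] + wh2 * res.final_state[1] +
              wpk * res.final_state[2];
        pk = wpk * res.final_state[2];
      }
      poly_total[r] = tot;
      poly_frac[r] = tot > 0.0 ? pk / tot : 0.0;
      poly_conv[r] = res.converged;
      poly_tc[r] = res.t_converged;
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["mono_total"] = mono_total, _["mono_prelk_frac"] = mono_frac,
      _["mono_converged"] = mono_conv, _["mono_t_converged"] = mono_tc,
      _["poly_total"] = poly_total, _["poly_prelk_frac"] = poly_frac,
      _["poly_converged"] = poly_conv, _["poly_t_converged"] = poly_tc);
}
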