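// Compiled core: model right-hand sides, fixed-step RK4 propagation and the
// sigma-point filter inner loop.  Reference R implementations of the same
// equations live in R/ and are tested for agreement with these routines.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Parameter vector layouts (kept in step with R/params.R)
//
// cell parameters, length 22:
//   0 C_m  1 g_Na  2 g_K  3 g_AHP  4 g_KL  5 g_NaL  6 g_ClL  7 phi
//   8 g_Ca 9 E_Ca 10 Cl_i 11 Cl_o 12 rho 13 G_glia 14 eps 15 K_bath
//  16 beta_vol 17 gamma 18 therm_mV 19 alpha_m_const 20 pin_K_o 21 pin_Na_i
//
// synapse parameters, length 14:
//   0 g_inh 1 g_exc 2 tau_e 3 tau_i 4 E_exc 5 E_inh 6 s_theta 7 s_slope
//   8 eta_theta 9 eta_slope 10 tau_eta 11 delta 12 eta_c 13 sigma_chi
//
// single-cell state, length 7: V m h n Ca K_o Na_i
// coupled-pair state, length 18: pc(0..6) in(7..13) s_p eta_p s_i eta_i
// ---------------------------------------------------------------------------

static const int NCELLPAR = 22;
static const int NSYNPAR  = 14;

// modes for the single-cell RHS
static const int MODE_FULL       = 0;
static const int MODE_FIXED_IONS = 1;
static const int MODE_CRIPPLED   = 2;

static inline double ratio_rate(double u, double scale, double k) {
  // scale*u / (1 - exp(-u/k)) with the removable singularity at u = 0
  if (std::fabs(u) < 1e-7) return scale * k;
  return scale * u / (-std::expm1(-u / k));
}

static inline void gating_rates(double V, double* r) {
  r[0] = ratio_rate(V + 30.0, 0.1, 10.0);            // alpha_m
  r[1] = 4.0 * std::exp(-(V + 55.0) / 18.0);         // beta_m
  r[2] = 0.07 * std::exp(-(V + 44.0) / 20.0);        // alpha_h
  r[3] = 1.0 / (1.0 + std::exp(-0.1 * (V + 14.0)));  // beta_h
  r[4] = ratio_rate(V + 34.0, 0.01, 10.0);           // alpha_n
  r[5] = 0.125 * std::exp(-(V + 44.0) / 80.0);       // beta_n
}

// single-cell derivative; Iext in uA/cm^2, lateralK in mM/s
static void rhs_single(const double* s, double* ds, const double* p,
                       int mode, double Iext, double lateralK) {
  const double V = s[0], m = s[1], h = s[2], n = s[3], Ca = s[4];
  double Ko = s[5], Nai = s[6];
  const double beta = p[16], therm = p[18];

  if (mode == MODE_FIXED_IONS) { Ko = p[20]; Nai = p[21]; }
  // guarded derived concentrations (electroneutrality / Na conservation)
  double Ki  = 140.0 + (18.0 - Nai);
  double Nao = 144.0 - beta * (Nai - 18.0);
  if (Ki  < 1.0)   Ki  = 1.0;
  if (Nao < 1.0)   Nao = 1.0;
  if (Ko  < 1e-6)  Ko  = 1e-6;
  const double E_K  = therm * std::log(Ko / Ki);
  const double E_Na = therm * std::log(Nao / Nai);
  const double E_Cl = therm * std::log(p[10] / p[11]);

  double r[6];
  gating_rates(V, r);
  if (mode == MODE_CRIPPLED) r[0] = p[19];

  const double I_Na = p[1] * m * m * m * h * (V - E_Na) + p[5] * (V - E_Na);
  const double I_K  = (p[2] * n * n * n * n + p[3] * Ca / (1.0 + Ca)) * (V - E_K)
                      + p[4] * (V - E_K);
  const double I_Cl = p[6] * (V - E_Cl);

  ds[0] = (-I_Na - I_K - I_Cl + Iext) / p[0];
  ds[1] = p[7] * (r[0] * (1.0 - m) - r[1] * m);
  ds[2] = p[7] * (r[2] * (1.0 - h) - r[3] * h);
  ds[3] = p[7] * (r[4] * (1.0 - n) - r[5] * n);
  ds[4] = -0.002 * p[8] * (V - p[9]) / (1.0 + std::exp(-(V + 25.0) / 2.5))
          - Ca / 80.0;

  if (mode == MODE_FIXED_IONS) {
    ds[5] = 0.0;
    ds[6] = 0.0;
  } else {
    const double pump = p[12] / ((1.0 + std::exp((25.0 - Nai) / 3.0)) *
                                 (1.0 + std::exp(5.5 - Ko)));
    const double glia = p[13] / (1.0 + std::exp((18.0 - Ko) / 2.5));
    const double diff = p[14] * (Ko - p[15]);
    // ion equations are per second; membrane time base is ms
    ds[5] = (p[17] * beta * I_K - 2.0 * beta * pump - glia - diff + lateralK) / 1000.0;
    ds[6] = (-p[17] * I_Na - 3.0 * pump) / 1000.0;
  }
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double chi_gate(double eta, const double* q) {
  return 1.0 / (1.0 + std::exp((eta - q[12]) / q[13]));
}

// coupled PC-IN derivative; both cells run the full model
static void rhs_pair(const double* s, double* ds, const double* ppc,
                     const double* pin, const double* q,
                     double Ipc, double Iin) {
  const double Vp = s[0], Vi = s[7];
  const double sp = s[14], etap = s[15], si = s[16], etai = s[17];

  const double Isyn_pc = -q[0] * si * chi_gate(etai, q) * (Vp - q[5]);
  const double Isyn_in = -q[1] * sp * chi_gate(etap, q) * (Vi - q[4]);
  const double latK = q[11] * (s[12] - s[5]);   // delta * (Ko_in - Ko_pc), mM/s

  rhs_single(s,     ds,     ppc, MODE_FULL, Ipc + Isyn_pc,  latK);
  rhs_single(s + 7, ds + 7, pin, MODE_FULL, Iin + Isyn_in, -latK);

  ds[14] = (logistic((Vp - q[6]) / q[7]) - sp)   / q[2];
  ds[15] = (logistic((Vp - q[8]) / q[9]) - etap) / q[10];
  ds[16] = (logistic((Vi - q[6]) / q[7]) - si)   / q[3];
  ds[17] = (logistic((Vi - q[8]) / q[9]) - etai) / q[10];
}

struct ModelCtx {
  int model;        // 0 = single cell, 1 = coupled pair
  int mode;         // single-cell variant
  const double* ppc;
  const double* pin;
  const double* psyn;
  double amp_pc, onset, dur, amp_in, base_pc, base_in;
};

static inline void eval_rhs(const ModelCtx& c, double t, const double* s, double* ds) {
  const bool on = (t >= c.onset) && (t < c.onset + c.dur);
  const double Ipc = c.base_pc + (on ? c.amp_pc : 0.0);
  const double Iin = c.base_in + (on ? c.amp_in : 0.0);
  if (c.model == 0) {
    rhs_single(s, ds, c.ppc, c.mode, Ipc, 0.0);
  } else {
    rhs_pair(s, ds, c.ppc, c.pin, c.psyn, Ipc, Iin);
  }
}

static void clamp_state(double* s, int model);

// classical RK4 step; `guard` additionally clamps the internal stages to
// the physical domain (used only by the filter, whose sigma points can
// visit extreme states where the stage estimates would overflow)
static inline void rk4_step(const ModelCtx& c, double t, double dt, double* s, int dim,
                            double* k1, double* k2, double* k3, double* k4, double* tmp,
                            bool guard = false) {
  eval_rhs(c, t, s, k1);
  for (int i = 0; i < dim; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
  if (guard) clamp_state(tmp, c.model);
  eval_rhs(c, t + 0.5 * dt, tmp, k2);
  for (int i = 0; i < dim; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
  if (guard) clamp_state(tmp, c.model);
  eval_rhs(c, t + 0.5 * dt, tmp, k3);
  for (int i = 0; i < dim; ++i) tmp[i] = s[i] + dt * k3[i];
  if (guard) clamp_state(tmp, c.model);
  eval_rhs(c, t + dt, tmp, k4);
  for (int i = 0; i < dim; ++i)
    s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// clamp a state vector to the model's physical domain (used only inside the
// filter, which is responsible for keeping estimates physical)
static void clamp_state(double* s, int model) {
  auto box = [](double& x, double lo, double hi) {
    if (x < lo) x = lo; else if (x > hi) x = hi;
  };
  int ncell = (model == 0) ? 1 : 2;
  for (int cell = 0; cell < ncell; ++cell) {
    double* u = s + 7 * cell;
    box(u[0], -150.0, 150.0);
    box(u[1], 0.0, 1.0); box(u[2], 0.0, 1.0); box(u[3], 0.0, 1.0);
    box(u[4], 0.0, 1e3);
    box(u[5], 0.1, 100.0);   // K_o
    box(u[6], 5.0, 38.0);    // Na_i (keeps derived K_i, Na_o positive)
  }
  if (model == 1) {
    box(s[14], 0.0, 1.0); box(s[16], 0.0, 1.0);
    box(s[15], 0.0, 10.0); box(s[17], 0.0, 10.0);
  }
}

// [[Rcpp::export]]
NumericVector cpp_rhs_single(NumericVector state, NumericVector pars,
                             int mode, double Iext, double lateralK) {
  NumericVector out(7);
  rhs_single(state.begin(), out.begin(), pars.begin(), mode, Iext, lateralK);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rhs_pair(NumericVector state, NumericVector pc_pars,
                           NumericVector in_pars, NumericVector syn_pars,
                           double Ipc, double Iin) {
  NumericVector out(18);
  rhs_pair(state.begin(), out.begin(), pc_pars.begin(), in_pars.begin(),
           syn_pars.begin(), Ipc, Iin);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gating_rates(double V) {
  NumericVector out(6);
  gating_rates(V, out.begin());
  return out;
}

// Fixed-step RK4 simulation.  Records every `record_every` steps (state at
// t0 is row 1).  Aborts with a partial result on divergence.
// [[Rcpp::export]]
List cpp_simulate(NumericVector x0, NumericVector pc_pars, NumericVector in_pars,
                  NumericVector syn_pars, int model, int mode, double t0,
                  double dt, int n_steps, int record_every, NumericVector stim) {
  const int dim = (model == 0) ? 7 : 18;
  ModelCtx c{model, mode, pc_pars.begin(), in_pars.begin(), syn_pars.begin(),
             stim[0], stim[1], stim[2], stim[3], stim[4], stim[5]};
  std::vector<double> s(x0.begin(), x0.end());
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), tmp(dim);

  const int n_rec = n_steps / record_every + 1;
  arma::mat out(n_rec, dim);
  for (int i = 0; i < dim; ++i) out(0, i) = s[i];

  int row = 1;
  bool ok = true;
  int done = 0;
  for (int k = 0; k < n_steps; ++k) {
    rk4_step(c, t0 + k * dt, dt, s.data(), dim,
             k1.data(), k2.data(), k3.data(), k4.data(), tmp.data());
    bool bad = false;
    for (int i = 0; i < dim; ++i) if (!std::isfinite(s[i])) bad = true;
    if (bad || std::fabs(s[0]) > 150.0 || (model == 1 && std::fabs(s[7]) > 150.0)) {
      ok = false;
      break;
    }
    done = k + 1;
    if ((k + 1) % record_every == 0 && row < n_rec) {
      for (int i = 0; i < dim; ++i) out(row, i) = s[i];
      ++row;
    }
  }
  if (row < n_rec) out = out.rows(0, row - 1);
  return List::create(_["states"] = out, _["ok"] = ok, _["steps_done"] = done);
}

// symmetrize + eigenvalue floor; mirrors condition_covariance() in R
static void condition_cov(arma::mat& P, double jitter) {
  P = 0.5 * (P + P.t());
  const double floor_val = jitter * arma::trace(P) / P.n_rows;
  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, P)) return;
  if (eval.min() < floor_val) {
    for (arma::uword i = 0; i < eval.n_elem; ++i)
      if (eval(i) < floor_val) eval(i) = floor_val;
    P = evec * arma::diagmat(eval) * evec.t();
    P = 0.5 * (P + P.t());
  }
}

static bool sqrt_cols(const arma::mat& P, double D, arma::mat& S, double jitter) {
  // columns of S satisfy S * S.t() = D * P
  arma::mat L;
  if (arma::chol(L, D * P, "lower")) { S = L; return true; }
  arma::mat Pc = P;
  condition_cov(Pc, std::max(jitter, 1e-12));
  if (arma::chol(L, D * Pc, "lower")) { S = L; return true; }
  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, D * Pc)) return false;
  eval.transform([](double v) { return v > 0.0 ? std::sqrt(v) : 0.0; });
  S = evec * arma::diagmat(eval);
  return true;
}

// Sigma-point filter over a voltage trace with the compiled model as the
// transition function.  Augmented state = [dynamic state, tracked params
// (log- or identity-transformed)].  Equal weights 1/(2D), 2D points, no
// central point; optional redraw of sigma points before the update.
// [[Rcpp::export]]
List cpp_ukf(NumericVector y, double t_first, double dt_obs, int n_sub, double dt,
             int model, int mode,
             NumericVector pc_pars, NumericVector in_pars, NumericVector syn_pars,
             NumericVector stim, int obs_index,
             IntegerVector tracked, LogicalVector log_transform,
             NumericVector x0, NumericMatrix P0in, NumericMatrix Qin, double Rv,
             bool redraw, double jitter, bool keep_sigma_cov,
             NumericVector par_lo, NumericVector par_hi) {
  const int nd = (model == 0) ? 7 : 18;
  const int np = tracked.size();
  const int D = nd + np;
  const int ns = 2 * D;
  const int n_obs = y.size();

  // writable copies of the parameter blocks for sigma-point propagation
  std::vector<double> ppc(pc_pars.begin(), pc_pars.end());
  std::vector<double> pin(in_pars.begin(), in_pars.end());
  std::vector<double> psn(syn_pars.begin(), syn_pars.end());

  arma::vec xhat(x0.begin(), D);
  arma::mat P(P0in.begin(), D, D);
  arma::mat Q(Qin.begin(), D, D);

  arma::mat means(n_obs, D), sds(n_obs, D);
  arma::vec innov(n_obs), ypred(n_obs), gain_norm(n_obs), min_eig(n_obs);

  arma::mat X(D, ns);          // sigma points
  std::vector<double> k1(nd), k2(nd), k3(nd), k4(nd), tmp(nd), st(nd);

  bool ok = true;
  int err_step = -1;

  // clamp parameter components (transformed scale) to their bounds
  auto clamp_pars = [&](arma::vec& x) {
    for (int j = 0; j < np; ++j) {
      if (x(nd + j) < par_lo[j]) x(nd + j) = par_lo[j];
      if (x(nd + j) > par_hi[j]) x(nd + j) = par_hi[j];
    }
  };
  auto set_tracked = [&](const arma::vec& x) {
    for (int j = 0; j < np; ++j) {
      double v = x(nd + j);
      if (v < par_lo[j]) v = par_lo[j];
      if (v > par_hi[j]) v = par_hi[j];
      if (log_transform[j]) v = std::exp(v);
      int idx = tracked[j];
      if (idx < NCELLPAR) ppc[idx] = v;
      else if (idx < 2 * NCELLPAR) pin[idx - NCELLPAR] = v;
      else psn[idx - 2 * NCELLPAR] = v;
    }
  };

  for (int k = 0; k < n_obs; ++k) {
    // --- sigma points from the posterior ---
    arma::mat S;
    if (!sqrt_cols(P, (double)D, S, jitter)) { ok = false; err_step = k; break; }
    for (int j = 0; j < D; ++j) {
      X.col(j)     = xhat + S.col(j);
      X.col(D + j) = xhat - S.col(j);
    }

    // --- propagate each sigma point across one observation interval ---
    const double tk = t_first + (double)(k - 1) * dt_obs;  // interval start
    for (int j = 0; j < ns; ++j) {
      arma::vec xj = X.col(j);
      set_tracked(xj);
      ModelCtx c{model, mode, ppc.data(), pin.data(), psn.data(),
                 stim[0], stim[1], stim[2], stim[3], stim[4], stim[5]};
      for (int i = 0; i < nd; ++i) st[i] = xj(i);
      clamp_state(st.data(), model);
      for (int m = 0; m < n_sub; ++m) {
        rk4_step(c, tk + m * dt, dt, st.data(), nd,
                 k1.data(), k2.data(), k3.data(), k4.data(), tmp.data(),
                 true);
        clamp_state(st.data(), model);   // keep sigma states physical
      }
      for (int i = 0; i < nd; ++i) xj(i) = st[i];
      for (int i = 0; i < nd; ++i)
        if (!std::isfinite(xj(i))) { ok = false; err_step = k; }
      X.col(j) = xj;   // parameter components untouched: trivial dynamics
    }
    if (!ok) break;

    // --- a priori moments ---
    arma::vec xt = arma::mean(X, 1);
    arma::mat Xc = X.each_col() - xt;
    arma::mat Pt = (Xc * Xc.t()) / (double)ns + Q;
    condition_cov(Pt, jitter);

    // --- measurement update (optionally with redrawn sigma points) ---
    if (redraw) {
      if (!sqrt_cols(Pt, (double)D, S, jitter)) { ok = false; err_step = k; break; }
      for (int j = 0; j < D; ++j) {
        X.col(j)     = xt + S.col(j);
        X.col(D + j) = xt - S.col(j);
      }
      Xc = X.each_col() - xt;
    }
    arma::rowvec yj = X.row(obs_index);
    const double ybar = arma::mean(yj);
    arma::rowvec yc = yj - ybar;
    const double Pyy = arma::dot(yc, yc) / (double)ns + Rv;
    arma::vec Pxy = (Xc * yc.t()) / (double)ns;

    arma::vec K = Pxy / Pyy;
    const double resid = y[k] - ybar;
    xhat = xt + K * resid;
    clamp_pars(xhat);
    P = Pt - (K * K.t()) * Pyy;
    condition_cov(P, jitter);

    means.row(k) = xhat.t();
    sds.row(k) = arma::sqrt(arma::clamp(P.diag(), 0.0, arma::datum::inf)).t();
    innov(k) = resid;
    ypred(k) = ybar;
    gain_norm(k) = arma::norm(K);
    if (keep_sigma_cov) {
      arma::vec ev = arma::eig_sym(P);
      min_eig(k) = ev.min();
    } else {
      min_eig(k) = NA_REAL;
    }
  }

  int n_done = ok ? n_obs : err_step;
  if (n_done < n_obs) {
    means = means.rows(0, std::max(n_done - 1, 0));
    sds = sds.rows(0, std::max(n_done - 1, 0));
    innov = innov.subvec(0, std::max(n_done - 1, 0));
    ypred = ypred.subvec(0, std::max(n_done - 1, 0));
    gain_norm = gain_norm.subvec(0, std::max(n_done - 1, 0));
    min_eig = min_eig.subvec(0, std::max(n_done - 1, 0));
  }
  return List::create(_["means"] = means, _["sds"] = sds, _["innovations"] = innov,
                      _["ypred"] = ypred, _["gain_norm"] = gain_norm,
                      _["min_eig"] = min_eig, _["P_final"] = P,
                      _["ok"] = ok, _["err_step"] = err_step + 1);
}
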