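#include <Rcpp.h>
using namespace Rcpp;

// Two-compartment disposition: macro constants (CL, Vc, Q, Vp) -> biexponential
// coefficients for the unit step (constant-rate infusion) response.
//
// During an infusion at rate R started at time 0:
//   C(t) = (R / Vc) * [ A (1 - exp(-l1 t)) + B (1 - exp(-l2 t)) ]
// with l1, l2 the roots of  l^2 - (k10 + k12 + k21) l + k10 k21 = 0,
//   A = (k21 - l1) / (l1 (l2 - l1)),  B = (k21 - l2) / (l2 (l1 - l2)).
// A + B = 1/k10, so C(inf) = R / CL (steady state sanity check).
struct Disp {
  double l1, l2, A, B, vc;
};

static Disp disposition(double cl, double vc, double q, double vp) {
  double k10 = cl / vc, k12 = q / vc, k21 = q / vp;
  double s = k10 + k12 + k21, p = k10 * k21;
  double disc = s * s - 4.0 * p;
  if (disc < 0.0) disc = 0.0;  // numerically impossible for positive params
  double sq = std::sqrt(disc);
  Disp d;
  d.l1 = 0.5 * (s + sq);
  d.l2 = 0.5 * (s - sq);
  d.A = (k21 - d.l1) / (d.l1 * (d.l2 - d.l1));
  d.B = (k21 - d.l2) / (d.l2 * (d.l1 - d.l2));
  d.vc = vc;
  return d;
}

static inline double step_resp(const Disp& d, double rate, double dt) {
  return rate / d.vc *
         (d.A * (-std::expm1(-d.l1 * dt)) + d.B * (-std::expm1(-d.l2 * dt)));
}

// Contribution of one infusion (rate over [on, off)) at time t. The
// post-infusion branch uses the analytic washout form
//   C = (R/Vc) [ A (1-e^{-l1 T}) e^{-l1 (t-off)} + ... ],  T = off - on,
// which decays gracefully instead of cancelling two saturated step
// responses far into the tail.
static inline double dose_conc(const Disp& d, double rate, double on,
                               double off, double t) {
  if (t <= on) return 0.0;
  if (t < off) return step_resp(d, rate, t - on);
  double T = off - on;
  return rate / d.vc *
         (d.A * (-std::expm1(-d.l1 * T)) * std::exp(-d.l1 * (t - off)) +
          d.B * (-std::expm1(-d.l2 * T)) * std::exp(-d.l2 * (t - off)));
}

// Concentration profile under linear superposition of zero-order infusions.
// Each infusion is a step input switched on at start[j] and off at
// start[j] + dur[j] (inclusive-exclusive).
// [[Rcpp::export]]
NumericVector cpp_conc_2cmt(double cl, double vc, double q, double vp,
                            NumericVector amt, NumericVector start,
                            NumericVector dur, NumericVector times) {
  Disp d = disposition(cl, vc, q, vp);
  R_xlen_t nt = times.size(), nd = amt.size();
  NumericVector out(nt);
  for (R_xlen_t j = 0; j < nd; ++j) {
    double rate = amt[j] / dur[j];
    double on = start[j], off = start[j] + dur[j];
    for (R_xlen_t i = 0; i < nt; ++i) {
      out[i] += dose_conc(d, rate, on, off, times[i]);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Laplace-approximation marginal likelihood for the population model.
//
// Individual parameters: CL_i = CL exp(eta_cl), Vc_i = Vc exp(eta_vc),
// eta ~ N(0, Omega) with Omega from (omega_cl, omega_vc, rho); additive
// Gaussian residual with SD sigma on the concentration scale.
// ---------------------------------------------------------------------------

struct Subject {
  NumericVector times, y, amt, start, dur;
};

struct InnerCtx {
  double cl, vc, q, vp, sig, sig2;
  // Omega^{-1} (2x2 upper-triangular storage; oi01 = off-diagonal)
  double oi00, oi01, oi11;
  int d;  // 1: eta_cl only; 2: (eta_cl, eta_vc)
  const Subject* s;
};

// Conditional data term: residual error is additive Gaussian truncated at
// zero (negative concentrations are physically impossible and the simulator
// resamples them), so each observation contributes
//   r^2/(2 sig^2) + log Phi(pred/sig)
// where the second term is the truncation normalizer.
static double cond_data_nll(const InnerCtx& c, const double* eta) {
  double cli = c.cl * std::exp(eta[0]);
  double vci = (c.d == 2) ? c.vc * std::exp(eta[1]) : c.vc;
  Disp d = disposition(cli, vci, c.q, c.vp);
  const NumericVector& t = c.s->times;
  double acc = 0.0;
  R_xlen_t nt = t.size(), nd = c.s->amt.size();
  for (R_xlen_t i = 0; i < nt; ++i) {
    double pred = 0.0;
    for (R_xlen_t j = 0; j < nd; ++j) {
      double rate = c.s->amt[j] / c.s->dur[j];
      double on = c.s->start[j], off = on + c.s->dur[j];
      pred += dose_conc(d, rate, on, off, t[i]);
    }
    if (pred < 0.0) pred = 0.0;
    double r = c.s->y[i] - pred;
    acc += 0.5 * r * r / c.sig2 + R::pnorm(pred / c.sig, 0.0, 1.0, 1, 1);
  }
  return acc;
}

// g(eta) = conditional data -loglik core + 0.5 eta' Oinv eta
static double g_core(const InnerCtx& c, const double* eta) {
  double quad;
  if (c.d == 2) {
    quad = c.oi00 * eta[0] * eta[0] + 2.0 * c.oi01 * eta[0] * eta[1] +
           c.oi11 * eta[1] * eta[1];
  } else {
    quad = c.oi00 * eta[0] * eta[0];
  }
  return cond_data_nll(c, eta) + 0.5 * quad;
}

// Damped Gauss-Newton search for the conditional mode of eta.
static void inner_mode(const InnerCtx& c, double* eta, double* gmin) {
  const double h = 1e-4;
  int d = c.d;
  for (int k = 0; k < d; ++k) eta[k] = 0.0;
  double g = g_core(c, eta);
  for (int it = 0; it < 60; ++it) {
    // numerical gradient and (finite-difference) Hessian of g
    double grad[2], H[3];  // H: [0]=H00 [1]=H01 [2]=H11
    double ep[2], em[2];
    double gp[2], gm[2];
    for (int k = 0; k < d; ++k) {
      for (int j = 0; j < d; ++j) { ep[j] = eta[j]; em[j] = eta[j]; }
      ep[k] += h; em[k] -= h;
      gp[k] = g_core(c, ep);
      gm[k] = g_core(c, em);
      grad[k] = (gp[k] - gm[k]) / (2.0 * h);
      if (k == 0) H[0] = (gp[0] - 2.0 * g + gm[0]) / (h * h);
      else H[2] = (gp[1] - 2.0 * g + gm[1]) / (h * h);
    }
    if (d == 2) {
      double epp[2] = {eta[0] + h, eta[1] + h}, epm[2] = {eta[0] + h, eta[1] - h};
      double emp[2] = {eta[0] - h, eta[1] + h}, emm[2] = {eta[0] - h, eta[1] - h};
      H[1] = (g_core(c, epp) - g_core(c, epm) - g_core(c, emp) + g_core(c, emm)) /
             (4.0 * h * h);
    }
    double gnorm = std::fabs(grad[0]);
    if (d == 2 && std::fabs(grad[1]) > gnorm) gnorm = std::fabs(grad[1]);
    if (gnorm < 1e-7 * (1.0 + std::fabs(g))) break;

    // Newton step with Levenberg damping to keep H positive definite
    double mu = 0.0, step[2] = {0.0, 0.0};
    for (int tries = 0; tries < 20; ++tries) {
      double a = H[0] + mu, bb = (d == 2) ? H[1] : 0.0, cc = (d == 2) ? H[2] + mu : 1.0;
      double det = (d == 2) ? a * cc - bb * bb : a;
      if (det > 1e-12 && a > 0.0) {
        if (d == 2) {
          step[0] = (cc * grad[0] - bb * grad[1]) / det;
          step[1] = (a * grad[1] - bb * grad[0]) / det;
        } else {
          step[0] = grad[0] / a;
        }
        break;
      }
      mu = (mu == 0.0) ? 1e-4 * (std::fabs(H[0]) + (d == 2 ? std::fabs(H[2]) : 0.0) + 1.0)
                       : mu * 10.0;
    }

    // backtracking line search
    double lam = 1.0, gnew = g, enew[2];
    bool ok = false;
    for (int ls = 0; ls < 15; ++ls) {
      for (int k = 0; k < d; ++k) enew[k] = eta[k] - lam * step[k];
      gnew = g_core(c, enew);
      if (gnew <= g + 1e-12) { ok = true; break; }
      lam *= 0.5;
    }
    if (!ok) break;
    double smax = std::fabs(lam * step[0]);
    if (d == 2 && std::fabs(lam * step[1]) > smax) smax = std::fabs(lam * step[1]);
    for (int k = 0; k < d; ++k) eta[k] = enew[k];
    g = gnew;
    if (smax < 1e-9) break;
  }
  *gmin = g;
}

// log|Hessian of g| at the mode via central second differences; falls back to
// the Gauss-Newton surrogate (prior precision, always PD) if indefinite.
static double log_det_hess(const InnerCtx& c, const double* eta, double g0) {
  const double h = 1e-3;
  int d = c.d;
  double H00, H11 = 0.0, H01 = 0.0;
  {
    double ep[2] = {eta[0] + h, d == 2 ? eta[1] : 0.0};
    double em[2] = {eta[0] - h, d == 2 ? eta[1] : 0.0};
    H00 = (g_core(c, ep) - 2.0 * g0 + g_core(c, em)) / (h * h);
  }
  if (d == 2) {
    double ep[2] = {eta[0], eta[1] + h}, em[2] = {eta[0], eta[1] - h};
    H11 = (g_core(c, ep) - 2.0 * g0 + g_core(c, em)) / (h * h);
    double epp[2] = {eta[0] + h, eta[1] + h}, epm[2] = {eta[0] + h, eta[1] - h};
    double emp[2] = {eta[0] - h, eta[1] + h}, emm[2] = {eta[0] - h, eta[1] - h};
    H01 = (g_core(c, epp) - g_core(c, epm) - g_core(c, emp) + g_core(c, emm)) /
          (4.0 * h * h);
    double det = H00 * H11 - H01 * H01;
    if (H00 > 0.0 && det > 0.0) return std::log(det);
  } else {
    if (H00 > 0.0) return std::log(H00);
  }
  // indefinite numerical Hessian: prior precision lower bound keeps the
  // objective finite and continuous
  if (d == 2) return std::log(c.oi00 * c.oi11 - c.oi01 * c.oi01);
  return std::log(c.oi00);
}

static void unpack_subjects(const List& subjects, std::vector<Subject>& out) {
  R_xlen_t n = subjects.size();
  out.resize(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    List s = subjects[i];
    out[i].times = s["times"];
    out[i].y = s["y"];
    out[i].amt = s["amt"];
    out[i].start = s["start"];
    out[i].dur = s["dur"];
  }
}

// par (transformed scale):
//   log CL, log Vc, log Q, log Vp, log omega_cl,
//   [log omega_vc, atanh(rho)]  (only when est_vc_iiv),
//   log sigma
// Returns the total negative log marginal likelihood (Laplace approximation).
// [[Rcpp::export]]
double cpp_poppk_nll(NumericVector par, List subjects, bool est_vc_iiv) {
  std::vector<Subject> subs;
  unpack_subjects(subjects, subs);

  InnerCtx c;
  c.cl = std::exp(par[0]);
  c.vc = std::exp(par[1]);
  c.q = std::exp(par[2]);
  c.vp = std::exp(par[3]);
  double w1 = std::exp(par[4]);
  double w2 = 0.0, rho = 0.0, sigma;
  double logdetO;
  if (est_vc_iiv) {
    w2 = std::exp(par[5]);
    rho = std::tanh(par[6]);
    sigma = std::exp(par[7]);
    double v1 = w1 * w1, v2 = w2 * w2, cv = rho * w1 * w2;
    double det = v1 * v2 - cv * cv;
    c.oi00 = v2 / det;
    c.oi01 = -cv / det;
    c.oi11 = v1 / det;
    logdetO = std::log(det);
    c.d = 2;
  } else {
    sigma = std::exp(par[5]);
    c.oi00 = 1.0 / (w1 * w1);
    c.oi01 = c.oi11 = 0.0;
    logdetO = 2.0 * std::log(w1);
    c.d = 1;
  }
  c.sig = sigma;
  c.sig2 = sigma * sigma;

  const double LOG2PI = 1.8378770664093453;
  double nll = 0.0;
  for (size_t i = 0; i < subs.size(); ++i) {
    c.s = &subs[i];
    double eta[2] = {0.0, 0.0}, gmin;
    inner_mode(c, eta, &gmin);
    double ldh = log_det_hess(c, eta, gmin);
    R_xlen_t n = subs[i].y.size();
    // -log L_i = g_full(mode) - (d/2) log 2pi + 0.5 log|H|
    //   with g_full = g_core + (n/2) log(2 pi sig2) + (d/2) log 2pi + 0.5 log|O|
    nll += gmin + 0.5 * n * (LOG2PI + std::log(c.sig2)) + 0.5 * logdetO + 0.5 * ldh;
  }
  return nll;
}

// Conditional modes (empirical Bayes estimates) of eta for each subject,
// given natural-scale model parameters.
// [[Rcpp::export]]
NumericMatrix cpp_poppk_ebes(double cl, double vc, double q, double vp,
                             double omega_cl, double omega_vc, double rho,
                             double sigma, List subjects, bool est_vc_iiv) {
  std::vector<Subject> subs;
  unpack_subjects(subjects, subs);
  InnerCtx c;
  c.cl = cl; c.vc = vc; c.q = q; c.vp = vp;
  c.sig = sigma;
  c.sig2 = sigma * sigma;
  if (est_vc_iiv) {
    double v1 = omega_cl * omega_cl, v2 = omega_vc * omega_vc;
    double cv = rho * omega_cl * omega_vc;
    double det = v1 * v2 - cv * cv;
    c.oi00 = v2 / det; c.oi01 = -cv / det; c.oi11 = v1 / det;
    c.d = 2;
  } else {
    c.oi00 = 1.0 / (omega_cl * omega_cl);
    c.oi01 = c.oi11 = 0.0;
    c.d = 1;
  }
  NumericMatrix out(subs.size(), 2);
  for (size_t i = 0; i < subs.size(); ++i) {
    c.s = &subs[i];
    double eta[2] = {0.0, 0.0}, gmin;
    inner_mode(c, eta, &gmin);
    out(i, 0) = eta[0];
    out(i, 1) = (c.d == 2) ? eta[1] : 0.0;
  }
  return out;
}
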