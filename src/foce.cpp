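// Core numerics: analytic one-compartment IV-infusion superposition and the
// FOCE-with-interaction marginal-likelihood contribution per subject.
// Kept in C++ because the outer optimiser evaluates the objective thousands
// of times (each evaluation re-solves every subject's inner eta problem).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double R_FLOOR = 1e-12;  // variance floor, guards f -> 0 under proportional error

// Concentration at time t from superposition of zero-order infusions with
// first-order elimination, ke = CL/V.
static double conc_point(double t,
                         const double* dt, const double* amt, const double* dur,
                         int nd, double CL, double V) {
  double ke = CL / V;
  double c = 0.0;
  for (int k = 0; k < nd; ++k) {
    double tau = t - dt[k];
    if (tau <= 0.0) continue;
    double r0 = amt[k] / dur[k];
    if (tau <= dur[k]) {
      c += (r0 / CL) * (1.0 - std::exp(-ke * tau));
    } else {
      c += (r0 / CL) * (1.0 - std::exp(-ke * dur[k])) * std::exp(-ke * (tau - dur[k]));
    }
  }
  return c;
}

// [[Rcpp::export]]
NumericVector conc_onecpt_cpp(NumericVector times,
                              NumericVector dose_time, NumericVector dose_amt,
                              NumericVector dose_dur,
                              double CL, double V) {
  int n = times.size(), nd = dose_time.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j)
    out[j] = conc_point(times[j], dose_time.begin(), dose_amt.begin(),
                        dose_dur.begin(), nd, CL, V);
  return out;
}

// Concentrations for one design evaluated over many (CL, V) draws:
// rows = times, cols = draws. Used by VPC/NPDE/dosing simulation.
// [[Rcpp::export]]
NumericMatrix conc_grid_cpp(NumericVector times,
                            NumericVector dose_time, NumericVector dose_amt,
                            NumericVector dose_dur,
                            NumericVector CL, NumericVector V) {
  int n = times.size(), m = CL.size(), nd = dose_time.size();
  NumericMatrix out(n, m);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      out(j, i) = conc_point(times[j], dose_time.begin(), dose_amt.begin(),
                             dose_dur.begin(), nd, CL[i], V[i]);
  return out;
}

struct SubjData {
  const double *y, *tobs;
  int nobs;
  const double *dt, *amt, *dur;
  int nd;
  double CLpop, Vpop;
  bool iiv_cl, iiv_v;
  double sp2, sa2;          // proportional and additive variance components
};

// model prediction vector at a given eta
static void predict_eta(const SubjData& s, const arma::vec& eta, arma::vec& f) {
  double ecl = 0.0, ev = 0.0;
  int k = 0;
  if (s.iiv_cl) ecl = eta(k++);
  if (s.iiv_v)  ev  = eta(k++);
  double CL = s.CLpop * std::exp(ecl);
  double V  = s.Vpop  * std::exp(ev);
  for (int j = 0; j < s.nobs; ++j)
    f(j) = conc_point(s.tobs[j], s.dt, s.amt, s.dur, s.nd, CL, V);
}

static inline double resvar(const SubjData& s, double f) {
  double r = s.sa2 + s.sp2 * f * f;
  return (r < R_FLOOR) ? R_FLOOR : r;
}

// Conditional (penalised extended least squares) objective:
//   sum_j [ (y_j - f_j)^2 / R_j + log R_j ] + eta' Omega^-1 eta
static double inner_obj(const SubjData& s, const arma::vec& eta,
                        const arma::vec& om2, arma::vec& fbuf) {
  predict_eta(s, eta, fbuf);
  double val = 0.0;
  for (int j = 0; j < s.nobs; ++j) {
    double r = resvar(s, fbuf(j));
    double e = s.y[j] - fbuf(j);
    val += e * e / r + std::log(r);
  }
  for (arma::uword k = 0; k < eta.n_elem; ++k)
    val += eta(k) * eta(k) / om2(k);
  return val;
}

// Damped Newton with finite-difference derivatives; deterministic:
// start at eta0, step-halving line search, gradient tolerance 1e-8.
static arma::vec inner_minimise(const SubjData& s, const arma::vec& om2,
                                const arma::vec& eta_start, double* obj_out) {
  int d = om2.n_elem;
  arma::vec eta = eta_start, fbuf(s.nobs);
  const double h = 1e-4;
  double obj = inner_obj(s, eta, om2, fbuf);

  for (int it = 0; it < 100; ++it) {
    arma::vec g(d);
    arma::mat H(d, d);
    // central differences for gradient and Hessian
    arma::vec ep = eta, em = eta;
    arma::vec fp(d), fm(d);
    for (int k = 0; k < d; ++k) {
      ep = eta; em = eta;
      ep(k) += h; em(k) -= h;
      fp(k) = inner_obj(s, ep, om2, fbuf);
      fm(k) = inner_obj(s, em, om2, fbuf);
      g(k) = (fp(k) - fm(k)) / (2.0 * h);
      H(k, k) = (fp(k) - 2.0 * obj + fm(k)) / (h * h);
    }
    if (d == 2) {
      arma::vec epp = eta; epp(0) += h; epp(1) += h;
      arma::vec emm = eta; emm(0) -= h; emm(1) -= h;
      double fpp = inner_obj(s, epp, om2, fbuf);
      double fmm = inner_obj(s, emm, om2, fbuf);
      double off = (fpp - fp(0) - fp(1) + 2.0 * obj - fm(0) - fm(1) + fmm) / (2.0 * h * h);
      H(0, 1) = H(1, 0) = off;
    }
    if (arma::norm(g, "inf") < 1e-8) break;

    arma::vec step;
    bool ok = false;
    // Newton direction if Hessian is PD, otherwise scaled gradient descent
    if (d == 1) {
      if (H(0, 0) > 1e-10) { step = -g / H(0, 0); ok = true; }
    } else {
      double det = H(0, 0) * H(1, 1) - H(0, 1) * H(0, 1);
      if (H(0, 0) > 1e-10 && det > 1e-12) {
        ok = arma::solve(step, H, g, arma::solve_opts::fast);
        if (ok) step = -step;
      }
    }
    if (!ok) step = -g / (arma::norm(g, "inf") + 1.0);
    if (arma::norm(step, "inf") > 5.0) step *= 5.0 / arma::norm(step, "inf");

    double alpha = 1.0, newobj = obj;
    arma::vec trial = eta;
    bool improved = false;
    for (int ls = 0; ls < 25; ++ls) {
      trial = eta + alpha * step;
      newobj = inner_obj(s, trial, om2, fbuf);
      if (std::isfinite(newobj) && newobj < obj) { improved = true; break; }
      alpha *= 0.5;
    }
    if (!improved) break;
    eta = trial;
    double rel = std::fabs(obj - newobj) / (std::fabs(obj) + 1.0);
    obj = newobj;
    if (rel < 1e-12) break;
  }
  *obj_out = obj;
  return eta;
}

// FOCE-I contribution for one subject. Linearisation about eta-hat:
//   G = df/deta at eta-hat, Sigma = G Omega G' + diag(R(eta-hat)),
//   r = y - f(eta-hat) + G eta-hat,
//   ofv_i = log det Sigma + r' Sigma^-1 r + n log(2 pi)
static bool subject_ofv(const SubjData& s, const arma::vec& om2,
                        arma::vec& eta,        // in: warm start, out: eta-hat
                        double* ofv,
                        arma::vec* pred, arma::vec* ipred, arma::vec* cwres) {
  int d = om2.n_elem, n = s.nobs;
  arma::vec fbuf(n);
  bool omega_zero = (d == 0) || arma::all(om2 < 1e-12);

  arma::vec etah;
  if (omega_zero) {
    etah = arma::zeros(std::max(d, 0));
  } else {
    double o1, o2;
    arma::vec e1 = inner_minimise(s, om2, eta, &o1);
    // second deterministic start guards against a bad warm start
    arma::vec e2 = inner_minimise(s, om2, arma::zeros(d), &o2);
    etah = (o1 <= o2) ? e1 : e2;
  }

  arma::vec fhat(n);
  if (omega_zero) {
    arma::vec zz(std::max(d, 1), arma::fill::zeros);
    predict_eta(s, zz, fhat);
  } else {
    predict_eta(s, etah, fhat);
  }

  arma::mat Sigma(n, n, arma::fill::zeros);
  arma::vec r(n);
  arma::mat G(n, std::max(d, 1), arma::fill::zeros);
  if (!omega_zero) {
    const double h = 1e-4;
    arma::vec fp(n), fm(n);
    for (int k = 0; k < d; ++k) {
      arma::vec ep = etah, em = etah;
      ep(k) += h; em(k) -= h;
      predict_eta(s, ep, fp);
      predict_eta(s, em, fm);
      G.col(k) = (fp - fm) / (2.0 * h);
    }
    Sigma = G.cols(0, d - 1) * arma::diagmat(om2) * G.cols(0, d - 1).t();
    r = arma::vec(const_cast<double*>(s.y), n, false) - fhat + G.cols(0, d - 1) * etah;
  } else {
    r = arma::vec(const_cast<double*>(s.y), n, false) - fhat;
  }
  for (int j = 0; j < n; ++j) Sigma(j, j) += resvar(s, fhat(j));

  arma::mat L;
  if (!arma::chol(L, arma::symmatu(Sigma), "lower")) return false;
  arma::vec u;
  if (!arma::solve(u, arma::trimatl(L), r, arma::solve_opts::fast)) return false;
  double ldet = 2.0 * arma::accu(arma::log(L.diag()));
  *ofv = ldet + arma::dot(u, u) + n * std::log(2.0 * M_PI);
  if (!std::isfinite(*ofv)) return false;

  if (pred) {
    arma::vec f0(n);
    arma::vec zeta(std::max(d, 1), arma::fill::zeros);
    predict_eta(s, zeta, f0);
    *pred = f0;
    *ipred = fhat;
    *cwres = u;
  }
  if (!omega_zero) eta = etah; else eta.zeros();
  return true;
}

static std::vector<SubjData> build_subjects(
    const NumericVector& y, const NumericVector& tobs, const IntegerVector& obs_ptr,
    const NumericVector& dtime, const NumericVector& damt, const NumericVector& ddur,
    const IntegerVector& dose_ptr,
    const NumericVector& CLpop, const NumericVector& Vpop,
    bool iiv_cl, bool iiv_v, double sp, double sa) {
  int N = CLpop.size();
  std::vector<SubjData> subs(N);
  for (int i = 0; i < N; ++i) {
    SubjData& s = subs[i];
    s.y = y.begin() + obs_ptr[i];
    s.tobs = tobs.begin() + obs_ptr[i];
    s.nobs = obs_ptr[i + 1] - obs_ptr[i];
    s.dt = dtime.begin() + dose_ptr[i];
    s.amt = damt.begin() + dose_ptr[i];
    s.dur = ddur.begin() + dose_ptr[i];
    s.nd = dose_ptr[i + 1] - dose_ptr[i];
    s.CLpop = CLpop[i];
    s.Vpop = Vpop[i];
    s.iiv_cl = iiv_cl;
    s.iiv_v = iiv_v;
    s.sp2 = sp * sp;
    s.sa2 = sa * sa;
  }
  return subs;
}

// Total FOCE-I objective over all subjects. eta_warm (N x d) carries warm
// starts between outer-optimiser evaluations; detail additionally returns
// PRED / IPRED / CWRES per observation.
// [[Rcpp::export]]
List foce_ofv_cpp(NumericVector y, NumericVector tobs, IntegerVector obs_ptr,
                  NumericVector dtime, NumericVector damt, NumericVector ddur,
                  IntegerVector dose_ptr,
                  NumericVector CLpop, NumericVector Vpop,
                  bool iiv_cl, bool iiv_v, NumericVector om2,
                  double sigma_prop, double sigma_add,
                  NumericMatrix eta_warm, bool detail = false) {
  int N = CLpop.size();
  int d = om2.size();
  std::vector<SubjData> subs = build_subjects(y, tobs, obs_ptr, dtime, damt, ddur,
                                              dose_ptr, CLpop, Vpop,
                                              iiv_cl, iiv_v, sigma_prop, sigma_add);
  arma::vec om2a(om2.begin(), d);
  NumericMatrix eta_out(N, std::max(d, 1));
  NumericVector ofv_i(N);
  int ntot = y.size();
  NumericVector pred(detail ? ntot : 0), ipred(detail ? ntot : 0), cwres(detail ? ntot : 0);

  double total = 0.0;
  int bad = -1;
  for (int i = 0; i < N; ++i) {
    arma::vec eta(std::max(d, 1), arma::fill::zeros);
    for (int k = 0; k < std::min<int>(d, eta_warm.ncol()); ++k) eta(k) = eta_warm(i, k);
    double o = 0.0;
    arma::vec pr, ip, cw;
    bool ok = subject_ofv(subs[i], om2a, eta, &o,
                          detail ? &pr : nullptr,
                          detail ? &ip : nullptr,
                          detail ? &cw : nullptr);
    if (!ok) { bad = i; break; }
    total += o;
    ofv_i[i] = o;
    for (int k = 0; k < eta_out.ncol(); ++k) eta_out(i, k) = (k < (int)eta.n_elem) ? eta(k) : 0.0;
    if (detail) {
      for (int j = 0; j < subs[i].nobs; ++j) {
        pred[obs_ptr[i] + j] = pr(j);
        ipred[obs_ptr[i] + j] = ip(j);
        cwres[obs_ptr[i] + j] = cw(j);
      }
    }
  }

  List out = List::create(_["ofv"] = (bad >= 0) ? R_PosInf : total,
                          _["eta"] = eta_out,
                          _["ofv_i"] = ofv_i,
                          _["failed_subject"] = bad + 1);
  if (detail) {
    out["pred"] = pred;
    out["ipred"] = ipred;
    out["cwres"] = cwres;
  }
  return out;
}
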