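// Laplace-approximated marginal likelihood for NLME fitting of
// sum-of-exponential (SOE) time-activity functions.
//
// Every SOE parameterisation is reduced to a term representation
//   f(t) = sum_k coef_k * exp(-rate_k * t)
// where the coefficients depend on the adjustable parameters and the rates
// already include the physical decay constant where the parameterisation
// adds it.  The last coefficient is set to minus the sum of the others so
// that f(0) = 0 holds exactly in floating point.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// model codes (keep in sync with R-side registry):
// 1 f3a, 2 f3b, 3 f3c, 4 f3d, 5 f4a, 6 f4b, 7 f4c, 8 f4d, 9 f4e, 10 f5a, 11 f5b
static bool soe_terms_c(const int model, const vec& p, const double lp,
                        const double lbc, vec& coef, vec& rate) {
  switch (model) {
  case 1: { // f3a: A1, lambda1, lambda2
    const double A = p(0), l1 = p(1), l2 = p(2);
    coef = { A, -A };
    rate = { l1 + lp, l2 + lp };
    break;
  }
  case 2: { // f3b: A1, lambda1, lambda2 (A1 carries inverse-TIA units)
    const double A = p(0), l1 = p(1), l2 = p(2);
    const double d = l2 - l1;
    if (A == 0.0 || d == 0.0) return false;
    const double c = ((l1 + lp) * (l2 + lp)) / (A * d);
    coef = { c, -c };
    rate = { l1 + lp, l2 + lp };
    break;
  }
  case 3: { // f3c: A1, lambda1, lambda2 (A1 is the TIA)
    const double A = p(0), l1 = p(1), l2 = p(2);
    const double d = l2 - l1;
    if (d == 0.0) return false;
    const double c = A * ((l1 + lp) * (l2 + lp)) / d;
    coef = { c, -c };
    rate = { l1 + lp, l2 + lp };
    break;
  }
  case 4: { // f3d: A1, lambda1, lambda2; no explicit physical-decay factor
    const double A = p(0), l1 = p(1), l2 = p(2);
    const double d = l2 - l1;
    if (A == 0.0 || d == 0.0) return false;
    const double c = (l1 * l2) / (A * d);
    coef = { c, -c };
    rate = { l1, l2 };
    break;
  }
  case 5: { // f4a: A1, A2, lambda1, lambda2
    const double A1 = p(0), A2 = p(1), l1 = p(2), l2 = p(3);
    coef = { A1, -A2, -(A1 - A2) };
    rate = { l1 + lp, l2 + lp, lbc + lp };
    break;
  }
  case 6: { // f4b: A1, alpha, lambda1, lambda2
    const double A = p(0), a = p(1), l1 = p(2), l2 = p(3);
    coef = { A * a, -A * (1.0 - a), -A * (2.0 * a - 1.0) };
    rate = { l1 + lp, l2 + lp, lbc + lp };
    break;
  }
  case 7: { // f4c: A1, alpha, lambda1, lambda2
    const double A = p(0), a = p(1), l1 = p(2), l2 = p(3);
    coef = { A * (1.0 - a), -A * a, -A * (1.0 - 2.0 * a) };
    rate = { l1 + lp, l2 + lp, lbc + lp };
    break;
  }
  case 8: { // f4d: A1, alpha, lambda1, lambda2 (A1 is the TIA)
    const double A = p(0), a = p(1), l1 = p(2), l2 = p(3);
    const double D = (1.0 - a) / (l1 + lp) - a / (l2 + lp)
      - (1.0 - 2.0 * a) / (lbc + lp);
    if (D == 0.0) return false;
    const double s = A / D;
    coef = { s * (1.0 - a), -s * a, -s * (1.0 - 2.0 * a) };
    rate = { l1 + lp, l2 + lp, lbc + lp };
    break;
  }
  case 9: { // f4e: A1, alpha, lambda1, lambda2 (A1 is the TIA)
    const double A = p(0), a = p(1), l1 = p(2), l2 = p(3);
    const double D = a / (l1 + lp) - (1.0 - a) / (l2 + lp)
      - (2.0 * a - 1.0) / (lbc + lp);
    if (D == 0.0) return false;
    const double s = A / D;
    coef = { s * a, -s * (1.0 - a), -s * (2.0 * a - 1.0) };
    rate = { l1 + lp, l2 + lp, lbc + lp };
    break;
  }
  case 10: { // f5a: A1, A2, lambda1, lambda2, lambda3
    const double A1 = p(0), A2 = p(1), l1 = p(2), l2 = p(3), l3 = p(4);
    coef = { A1, -A2, -(A1 - A2) };
    rate = { l1 + lp, l2 + lp, l3 + lp };
    break;
  }
  case 11: { // f5b: A1, A2, A3, lambda1, lambda2
    const double A1 = p(0), A2 = p(1), A3 = p(2), l1 = p(3), l2 = p(4);
    coef = { A1, A2, -A3, -(A1 + A2 - A3) };
    rate = { l1 + lp, lp, l2 + lp, lbc + lp };
    break;
  }
  default:
    return false;
  }
  const uword K = coef.n_elem;
  coef(K - 1) = -accu(coef.head(K - 1)); // exact f(0) = 0
  return coef.is_finite() && rate.is_finite();
}

// [[Rcpp::export]]
Rcpp::List cpp_soe_terms(const int model, const arma::vec& params,
                         const double lambda_phys, const double lambda_bc) {
  vec coef, rate;
  const bool ok = soe_terms_c(model, params, lambda_phys, lambda_bc, coef, rate);
  return Rcpp::List::create(Rcpp::Named("ok") = ok,
                            Rcpp::Named("coef") = coef,
                            Rcpp::Named("rate") = rate);
}

// [[Rcpp::export]]
arma::vec cpp_soe_eval(const int model, const arma::vec& params,
                       const arma::vec& times, const double lambda_phys,
                       const double lambda_bc) {
  vec coef, rate;
  vec out(times.n_elem);
  if (!soe_terms_c(model, params, lambda_phys, lambda_bc, coef, rate)) {
    out.fill(datum::nan);
    return out;
  }
  for (uword i = 0; i < times.n_elem; ++i) {
    double f = 0.0;
    for (uword k = 0; k < coef.n_elem; ++k)
      f += coef(k) * std::exp(-rate(k) * times(i));
    out(i) = f;
  }
  return out;
}

// log f(t; P); false when f <= 0 at any time (log-residual undefined)
static bool log_pred(const int model, const vec& P, const double lp,
                     const double lbc, const vec& t, vec& out) {
  vec coef, rate;
  if (!soe_terms_c(model, P, lp, lbc, coef, rate)) return false;
  out.set_size(t.n_elem);
  for (uword i = 0; i < t.n_elem; ++i) {
    double f = 0.0;
    for (uword k = 0; k < coef.n_elem; ++k)
      f += coef(k) * std::exp(-rate(k) * t(i));
    if (!(f > 0.0) || !std::isfinite(f)) return false;
    out(i) = std::log(f);
  }
  return true;
}

// penalised inner objective Q(eta) = ||r||^2/s2 + sum_free eta_j^2/om2_j
static bool inner_Q(const int model, const vec& tvp, const vec& om2,
                    const double s2, const double lp, const double lbc,
                    const vec& t, const vec& logy, const uvec& free,
                    const vec& eta, double& Q, vec& r) {
  const vec P = tvp % exp(eta);
  vec m;
  if (!log_pred(model, P, lp, lbc, t, m)) return false;
  r = logy - m;
  Q = dot(r, r) / s2;
  for (uword k = 0; k < free.n_elem; ++k) {
    const uword j = free(k);
    Q += eta(j) * eta(j) / om2(j);
  }
  return std::isfinite(Q);
}

// Jacobian of the residual r(eta) w.r.t. the free etas (forward differences)
static bool inner_J(const int model, const vec& tvp, const vec& om2,
                    const double s2, const double lp, const double lbc,
                    const vec& t, const vec& logy, const uvec& free,
                    const vec& eta, const vec& r0, mat& J) {
  const double h = 1e-6;
  J.set_size(t.n_elem, free.n_elem);
  vec m;
  for (uword k = 0; k < free.n_elem; ++k) {
    vec e = eta;
    e(free(k)) += h;
    vec P = tvp % exp(e);
    if (log_pred(model, P, lp, lbc, t, m)) {
      J.col(k) = ((logy - m) - r0) / h;
      continue;
    }
    // forward step infeasible (prediction <= 0): backward difference
    e = eta;
    e(free(k)) -= h;
    P = tvp % exp(e);
    if (!log_pred(model, P, lp, lbc, t, m)) return false;
    J.col(k) = (r0 - (logy - m)) / h;
  }
  return true;
}

// Damped Gauss-Newton solve of the inner (MAP) problem for one patient.
// On success fills eta (free components updated), Q, and Hhalf = J'J/s2 + D.
static bool inner_solve(const int model, const vec& tvp, const vec& om2,
                        const double s2, const double lp, const double lbc,
                        const vec& t, const vec& logy, const uvec& free,
                        vec& eta, double& Q, mat& Hhalf) {
  const uword nf = free.n_elem;
  vec r;
  if (!inner_Q(model, tvp, om2, s2, lp, lbc, t, logy, free, eta, Q, r)) {
    eta.zeros();
    if (!inner_Q(model, tvp, om2, s2, lp, lbc, t, logy, free, eta, Q, r))
      return false;
  }
  if (nf == 0) { Hhalf.set_size(0, 0); return true; }

  vec dinv(nf);
  for (uword k = 0; k < nf; ++k) dinv(k) = 1.0 / om2(free(k));
  mat J;
  double mu = 0.0;
  // when the mode sits against the feasibility boundary (prediction -> 0)
  // a failed line search or Jacobian means "stay where we are", not an
  // error: the current point is accepted with its Gauss-Newton curvature
  const auto finish = [&](bool haveJ) {
    if (!haveJ &&
        !inner_J(model, tvp, om2, s2, lp, lbc, t, logy, free, eta, r, J)) {
      Hhalf = diagmat(dinv); // prior curvature only (rare fallback)
      return true;
    }
    Hhalf = J.t() * J / s2 + diagmat(dinv);
    return true;
  };
  for (int it = 0; it < 100; ++it) {
    if (!inner_J(model, tvp, om2, s2, lp, lbc, t, logy, free, eta, r, J)) {
      Hhalf = diagmat(dinv);
      return true;
    }
    vec etaf(nf);
    for (uword k = 0; k < nf; ++k) etaf(k) = eta(free(k));
    const mat A = J.t() * J / s2 + diagmat(dinv);
    const vec g = J.t() * r / s2 + dinv % etaf; // gradient of Q/2
    if (norm(g, "inf") < 1e-10) { Hhalf = A; return true; }
    bool accepted = false;
    for (int ls = 0; ls < 16; ++ls) {
      vec delta;
      const bool solved = solve(delta, A + mu * eye(nf, nf), -g,
                                solve_opts::no_approx + solve_opts::likely_sympd);
      if (solved) {
        vec etry = eta;
        for (uword k = 0; k < nf; ++k) etry(free(k)) += delta(k);
        double Qtry;
        vec rtry;
        if (inner_Q(model, tvp, om2, s2, lp, lbc, t, logy, free, etry, Qtry, rtry)
            && Qtry <= Q + 1e-12) {
          const double step = norm(delta, "inf");
          eta = etry; Q = Qtry; r = rtry;
          mu = std::max(mu / 3.0, 0.0);
          accepted = true;
          if (step < 1e-9) return finish(false);
          break;
        }
      }
      mu = (mu == 0.0) ? 1e-4 : mu * 8.0;
      if (mu > 1e12) break;
    }
    if (!accepted) return finish(true);
  }
  return finish(false);
}

// Laplace-approximated -2 log marginal likelihood for the whole cohort.
//
// start: 0-based first row of each patient's block; len: block lengths.
// omega2 entries equal to 0 pin the corresponding random effect at 0
// (its prior and log-det contributions are dropped).
// [[Rcpp::export]]
Rcpp::List cpp_laplace_ofv(const int model, const arma::vec& tvp,
                           const arma::vec& omega2, const double sigma2,
                           const arma::vec& times, const arma::vec& logy,
                           const arma::ivec& start, const arma::ivec& len,
                           const arma::mat& eta_start,
                           const double lambda_phys, const double lambda_bc) {
  const uword M = start.n_elem;
  const uword p = tvp.n_elem;
  std::vector<uword> freev;
  for (uword j = 0; j < p; ++j) if (omega2(j) > 0.0) freev.push_back(j);
  const uvec free = conv_to<uvec>::from(freev);
  const uword nf = free.n_elem;

  mat etas(p, M, fill::zeros);
  double ofv = 0.0;
  bool ok = true;
  double logprior_const = 0.0;
  for (uword k = 0; k < nf; ++k)
    logprior_const += std::log(2.0 * datum::pi * omega2(free(k)));

  for (uword m = 0; m < M && ok; ++m) {
    const uword a = (uword)start(m);
    const uword n = (uword)len(m);
    const vec t = times.subvec(a, a + n - 1);
    const vec ly = logy.subvec(a, a + n - 1);
    vec eta = (eta_start.n_cols == M && eta_start.n_rows == p)
      ? vec(eta_start.col(m)) : vec(p, fill::zeros);
    double Q;
    mat Hhalf;
    if (!inner_solve(model, tvp, omega2, sigma2, lambda_phys, lambda_bc,
                     t, ly, free, eta, Q, Hhalf)) {
      ok = false;
      break;
    }
    etas.col(m) = eta;
    double contrib = Q + n * std::log(2.0 * datum::pi * sigma2) + logprior_const;
    if (nf > 0) {
      double ld, sign;
      log_det(ld, sign, Hhalf);
      if (sign <= 0.0 || !std::isfinite(ld)) { ok = false; break; }
      contrib += ld - nf * LOG2PI;
    }
    ofv += contrib;
  }
  if (!std::isfinite(ofv)) ok = false;
  return Rcpp::List::create(Rcpp::Named("ok") = ok,
                            Rcpp::Named("ofv") = ok ? ofv : NA_REAL,
                            Rcpp::Named("etas") = etas);
}

// MAP (empirical-Bayes) random effects for a single patient given fixed
// population parameters.
// [[Rcpp::export]]
Rcpp::List cpp_inner_map(const int model, const arma::vec& tvp,
                         const arma::vec& omega2, const double sigma2,
                         const arma::vec& times, const arma::vec& logy,
                         const arma::vec& eta_start,
                         const double lambda_phys, const double lambda_bc) {
  const uword p = tvp.n_elem;
  std::vector<uword> freev;
  for (uword j = 0; j < p; ++j) if (omega2(j) > 0.0) freev.push_back(j);
  const uvec free = conv_to<uvec>::from(freev);
  vec eta = (eta_start.n_elem == p) ? vec(eta_start) : vec(p, fill::zeros);
  if (times.n_elem == 0) {
    return Rcpp::List::create(Rcpp::Named("ok") = true,
                              Rcpp::Named("eta") = vec(p, fill::zeros),
                              Rcpp::Named("Q") = 0.0);
  }
  double Q;
  mat Hhalf;
  const bool ok = inner_solve(model, tvp, omega2, sigma2, lambda_phys,
                              lambda_bc, times, logy, free, eta, Q, Hhalf);
  return Rcpp::List::create(Rcpp::Named("ok") = ok,
                            Rcpp::Named("eta") = eta,
                            Rcpp::Named("Q") = ok ? Q : NA_REAL);
}
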