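#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Newton-Raphson maximiser of the Cox partial likelihood with the Breslow
// approximation for tied event times.
//
// Xt holds variables in rows and patients in columns (the SurvivalCohort
// assay orientation), with columns sorted by increasing follow-up time;
// `cols` selects the active variables (0-based rows of Xt).  Keeping the
// patient dimension contiguous makes the risk-set accumulation cache
// friendly, and passing row indices avoids materialising submatrices for
// the thousands of leave-one-out fits of the elimination loop.
//
// The linear predictor is shifted by its maximum before exponentiation so
// large coefficients cannot overflow; the shift cancels everywhere.

static double cox_eval(const arma::mat& Xt, const arma::vec& time,
                       const arma::vec& status, const arma::vec& beta,
                       arma::vec& grad, arma::mat& hess) {
  const arma::uword n = Xt.n_cols;
  const arma::uword p = Xt.n_rows;

  arma::vec lp = Xt.t() * beta;
  const double shift = lp.max();

  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);
  double ll = 0.0;
  grad.zeros();
  hess.zeros();
  arma::vec sumx(p);

  arma::sword i = static_cast<arma::sword>(n) - 1;
  while (i >= 0) {
    const double t = time(i);
    arma::sword j = i;
    int d = 0;
    double sumlp = 0.0;
    sumx.zeros();
    while (j >= 0 && time(j) == t) {
      const double wj = std::exp(lp(j) - shift);
      const double* xj = Xt.colptr(j);
      S0 += wj;
      for (arma::uword a = 0; a < p; ++a) {
        const double wxa = wj * xj[a];
        S1(a) += wxa;
        double* s2a = S2.colptr(a);
        for (arma::uword b = a; b < p; ++b) s2a[b] += wxa * xj[b];
      }
      if (status(j) == 1.0) {
        ++d;
        sumlp += lp(j) - shift;
        for (arma::uword a = 0; a < p; ++a) sumx(a) += xj[a];
      }
      --j;
    }
    if (d > 0) {
      ll += sumlp - d * std::log(S0);
      const double invS0 = 1.0 / S0;
      const double dd = static_cast<double>(d);
      arma::vec r = S1 * invS0;
      grad += sumx - dd * r;
      const double dInvS0 = dd * invS0;
      for (arma::uword a = 0; a < p; ++a) {
        double* ha = hess.colptr(a);
        const double* s2a = S2.colptr(a);
        const double* rp = r.memptr();
        const double dra = dd * rp[a];
        for (arma::uword b = a; b < p; ++b)
          ha[b] -= dInvS0 * s2a[b] - dra * rp[b];
      }
    }
    i = j;
  }
  hess = arma::symmatl(hess);
  return ll;
}

// log-likelihood only: no S1/S2 accumulation, used for line search and the
// final convergence check (an order of magnitude cheaper per pass)
static double cox_ll(const arma::mat& Xt, const arma::vec& time,
                     const arma::vec& status, const arma::vec& beta) {
  const arma::uword n = Xt.n_cols;
  arma::vec lp = Xt.t() * beta;
  const double shift = lp.max();
  double S0 = 0.0;
  double ll = 0.0;
  arma::sword i = static_cast<arma::sword>(n) - 1;
  while (i >= 0) {
    const double t = time(i);
    arma::sword j = i;
    int d = 0;
    double sumlp = 0.0;
    while (j >= 0 && time(j) == t) {
      S0 += std::exp(lp(j) - shift);
      if (status(j) == 1.0) {
        ++d;
        sumlp += lp(j) - shift;
      }
      --j;
    }
    if (d > 0) ll += sumlp - d * std::log(S0);
    i = j;
  }
  return ll;
}

// [[Rcpp::export(name = ".cox_fit_breslow")]]
Rcpp::List cox_fit_breslow(const arma::mat& Xt, const arma::vec& time,
                           const arma::vec& status,
                           const arma::uvec& cols,
                           Rcpp::Nullable<Rcpp::NumericVector> init =
                               R_NilValue,
                           int maxIter = 30, double tol = 1e-10,
                           bool wantVcov = true) {
  const arma::uword p = cols.n_elem;
  const arma::uword n = Xt.n_cols;

  // one contiguous copy of the active variables; all Newton passes then
  // run cache-friendly over it
  arma::mat A = Xt.rows(cols);

  // degenerate (constant) covariate -> unusable fit, never an exception
  for (arma::uword a = 0; a < p; ++a) {
    const double x0 = A(a, 0);
    bool constant = true;
    for (arma::uword j = 1; j < n; ++j)
      if (A(a, j) != x0) { constant = false; break; }
    if (constant) {
      Rcpp::NumericVector nab(p, NA_REAL);
      return Rcpp::List::create(
          Rcpp::Named("beta") = nab, Rcpp::Named("loglik") = R_NegInf,
          Rcpp::Named("loglik0") = NA_REAL,
          Rcpp::Named("vcov") = R_NilValue,
          Rcpp::Named("converged") = false, Rcpp::Named("iter") = 0,
          Rcpp::Named("diagnostics") = "degenerate (constant) covariate");
    }
  }

  arma::vec beta(p, arma::fill::zeros);
  const bool haveInit = init.isNotNull();
  if (haveInit) {
    Rcpp::NumericVector b0(init);
    if (static_cast<arma::uword>(b0.size()) == p)
      beta = Rcpp::as<arma::vec>(b0);
  }
  arma::vec grad(p);
  arma::mat hess(p, p);

  double ll = cox_eval(A, time, status, beta, grad, hess);
  const double ll0 = haveInit ? NA_REAL : ll;  // beta starts at 0 otherwise
  bool converged = false;
  bool ok = true;
  int iter = 0;

  bool derivAtOptimum = true;
  for (iter = 1; iter <= maxIter; ++iter) {
    arma::vec step;
    const bool solved = arma::solve(
        step, -hess, grad,
        arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
    if (!solved || !step.is_finite()) { ok = false; break; }

    arma::vec nb = beta + step;
    double nll = cox_ll(A, time, status, nb);
    int halvings = 0;
    while ((!std::isfinite(nll) || nll < ll - 1e-12) && halvings < 30) {
      step *= 0.5;
      nb = beta + step;
      nll = cox_ll(A, time, status, nb);
      ++halvings;
    }
    if (!std::isfinite(nll)) { ok = false; break; }

    const double change = nll - ll;
    beta = nb;
    ll = nll;
    if (std::fabs(change) < tol * (std::fabs(ll) + 0.1)) {
      converged = true;
      derivAtOptimum = false;  // grad/hess still refer to the previous point
      break;
    }
    ll = cox_eval(A, time, status, beta, grad, hess);
  }

  if (!beta.is_finite() || arma::abs(beta).max() > 25.0) converged = false;
  if (!ok) converged = false;

  Rcpp::RObject vcov = R_NilValue;
  if (wantVcov) {
    if (!derivAtOptimum)
      cox_eval(A, time, status, beta, grad, hess);
    arma::mat vc(p, p);
    arma::mat negh = -hess;
    if (arma::inv_sympd(vc, negh)) {
      vcov = Rcpp::wrap(vc);
    } else {
      converged = false;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("beta") = beta, Rcpp::Named("loglik") = ll,
      Rcpp::Named("loglik0") = ll0, Rcpp::Named("vcov") = vcov,
      Rcpp::Named("converged") = converged, Rcpp::Named("iter") = iter,
      Rcpp::Named("diagnostics") =
          converged ? "" : "Newton-Raphson did not converge");
}
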