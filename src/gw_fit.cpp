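// Local weighted Poisson fits for geographically weighted regression.
// One Fisher-scoring fit per row of the geographic weight matrix; this is
// the inner loop of the semiparametric back-fitting algorithm and of the
// bandwidth search, so it lives in compiled code.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double ETA_CLAMP = 30.0;

// Weighted Poisson Fisher scoring on a subset of observations.
// Maximises sum_j w_j [ y_j (eta_j) - exp(eta_j) ] with eta = X b + o.
// Returns convergence flag; fills beta, M1 = X' diag(w mu) X and mu.
static bool fisher_poisson(const arma::vec& y, const arma::mat& X,
                           const arma::vec& o, const arma::vec& w,
                           double tol, int maxit,
                           arma::vec& beta, arma::mat& M1, arma::vec& mu,
                           const arma::vec* warm = nullptr) {
  const arma::uword p = X.n_cols;
  beta.zeros(p);
  if (warm != nullptr && warm->is_finite()) {
    beta = *warm;
  } else {
    // start from weighted-mean intercept when the first column is constant
    double ybar = arma::dot(w, y) / arma::accu(w);
    if (ybar > 0 && arma::all(X.col(0) == X(0, 0)) && X(0, 0) != 0.0) {
      beta(0) = std::log(ybar) / X(0, 0);
    }
  }
  arma::vec eta = X * beta + o;
  for (int it = 0; it < maxit; ++it) {
    eta = arma::clamp(eta, -ETA_CLAMP, ETA_CLAMP);
    mu = arma::exp(eta);
    arma::vec wm = w % mu;                      // IRLS weights
    arma::vec z = (eta - o) + (y - mu) / mu;    // working response (offset removed)
    M1 = X.t() * (X.each_col() % wm);
    arma::vec rhs = X.t() * (wm % z);
    arma::vec bnew;
    bool ok = arma::solve(bnew, M1, rhs, arma::solve_opts::no_approx);
    if (!ok || !bnew.is_finite()) return false;
    double step = arma::abs(bnew - beta).max();
    beta = bnew;
    eta = X * beta + o;
    if (step < tol) {
      eta = arma::clamp(eta, -ETA_CLAMP, ETA_CLAMP);
      mu = arma::exp(eta);
      wm = w % mu;
      M1 = X.t() * (X.each_col() % wm);
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_local_fits(const arma::vec& y, const arma::mat& X,
                    const arma::vec& offset, const arma::mat& W,
                    double tol = 1e-8, int maxit = 50,
                    bool sandwich = true,
                    Rcpp::Nullable<Rcpp::NumericMatrix> beta_init = R_NilValue) {
  // one local regression per ROW of W (rows = regression locations;
  // a single-row W fits one standalone local regression)
  const arma::uword nloc = W.n_rows, p = X.n_cols;
  arma::mat beta(nloc, p, arma::fill::value(NA_REAL));
  arma::mat se(nloc, p, arma::fill::value(NA_REAL));
  arma::vec hat_ii(nloc, arma::fill::value(NA_REAL));
  arma::vec eta_own(nloc, arma::fill::value(NA_REAL));
  LogicalVector ok(nloc);
  arma::mat binit;
  bool has_init = beta_init.isNotNull();
  if (has_init) binit = Rcpp::as<arma::mat>(beta_init.get());

  for (arma::uword i = 0; i < nloc; ++i) {
    arma::rowvec wi = W.row(i);
    arma::uvec idx = arma::find(wi > 0);
    if (idx.n_elem < p) { ok[i] = false; continue; }
    arma::vec ys = y(idx);
    arma::mat Xs = X.rows(idx);
    arma::vec os = offset(idx);
    arma::vec ws = wi(idx).as_col();

    arma::vec b; arma::mat M1; arma::vec mu;
    arma::vec warm;
    const arma::vec* warm_p = nullptr;
    if (has_init) { warm = binit.row(i).t(); warm_p = &warm; }
    bool conv = fisher_poisson(ys, Xs, os, ws, tol, maxit, b, M1, mu, warm_p);
    if (!conv) { ok[i] = false; continue; }

    arma::mat M1inv;
    if (!arma::inv_sympd(M1inv, M1)) {
      if (!arma::inv(M1inv, M1)) { ok[i] = false; continue; }
    }
    arma::vec sdiag;
    if (sandwich) {
      arma::vec w2m = arma::square(ws) % mu;
      arma::mat M2 = Xs.t() * (Xs.each_col() % w2m);
      arma::mat C = M1inv * M2 * M1inv;
      sdiag = C.diag();
    } else {
      sdiag = M1inv.diag();
    }
    if (sdiag.min() < 0) { ok[i] = false; continue; }

    beta.row(i) = b.t();
    se.row(i) = arma::sqrt(sdiag).t();

    // own observation inside the subset (weight at self is 1 by
    // construction when W is the square n x n weight matrix)
    arma::uvec self = arma::find(idx == i);
    if (W.n_rows != y.n_elem) self.reset();
    if (self.n_elem == 1) {
      arma::uword s = self(0);
      arma::rowvec xi = Xs.row(s);
      double lin = arma::as_scalar(xi * b);
      eta_own(i) = lin;
      double mui = mu(s);
      hat_ii(i) = arma::as_scalar(xi * M1inv * xi.t()) * ws(s) * mui;
    }
    ok[i] = true;
  }

  return List::create(_["beta"] = beta, _["se"] = se,
                      _["hat_ii"] = hat_ii, _["eta_own"] = eta_own,
                      _["ok"] = ok);
}
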