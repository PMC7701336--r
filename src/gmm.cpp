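// EM core for Gaussian mixtures with tied / diag / full covariance
// structures.  The sweep over (covariance type, k) at cohort scale is the
// hot loop of the pipeline, hence compiled.  All randomness (restart
// seeding) lives on the R side; this file is deterministic given its inputs.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// cov_type codes: 0 = tied, 1 = diag, 2 = full

// log N(x | mu, Sigma) for all rows of X, one component, via Cholesky.
static arma::vec log_gauss_full(const arma::mat& X, const arma::rowvec& mu,
                                const arma::mat& Sigma) {
  const arma::uword d = X.n_cols;
  arma::mat L;
  if (!arma::chol(L, Sigma, "lower"))
    stop("covariance matrix not positive definite");
  arma::mat centred = X.each_row() - mu;           // n x d
  arma::mat z = arma::solve(arma::trimatl(L), centred.t());  // d x n
  arma::vec quad = arma::sum(arma::square(z), 0).t();
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  return -0.5 * (d * std::log(2.0 * M_PI) + logdet + quad);
}

static arma::vec log_gauss_diag(const arma::mat& X, const arma::rowvec& mu,
                                const arma::rowvec& var) {
  const arma::uword d = X.n_cols;
  arma::mat centred = X.each_row() - mu;
  arma::mat sq = arma::square(centred);
  sq.each_row() /= var;
  arma::vec quad = arma::sum(sq, 1);
  double logdet = arma::accu(arma::log(var));
  return -0.5 * (d * std::log(2.0 * M_PI) + logdet + quad);
}

// weighted log densities, n x k
static arma::mat weighted_log_prob(const arma::mat& X, const arma::vec& w,
                                   const arma::mat& means, int cov_type,
                                   const arma::cube& covs,
                                   const arma::mat& dvars) {
  const arma::uword n = X.n_rows, k = means.n_rows;
  arma::mat lp(n, k);
  for (arma::uword j = 0; j < k; ++j) {
    arma::vec lg;
    if (cov_type == 1) {
      lg = log_gauss_diag(X, means.row(j), dvars.row(j));
    } else {
      const arma::mat& S = (cov_type == 0) ? covs.slice(0) : covs.slice(j);
      lg = log_gauss_full(X, means.row(j), S);
    }
    lp.col(j) = lg + std::log(w(j));
  }
  return lp;
}

// row-wise logsumexp; also writes responsibilities into resp
static double log_resp(const arma::mat& lp, arma::mat& resp) {
  arma::vec m = arma::max(lp, 1);
  arma::mat shifted = lp.each_col() - m;
  arma::vec lse = m + arma::log(arma::sum(arma::exp(shifted), 1));
  resp = arma::exp(lp.each_col() - lse);
  return arma::accu(lse);
}

// [[Rcpp::export(name = ".gmm_em_cpp")]]
List gmm_em_cpp(const arma::mat& X, const arma::mat& means0, int cov_type,
                double tol, int max_iter, double reg_covar,
                Rcpp::Nullable<Rcpp::NumericVector> weights0 = R_NilValue,
                Rcpp::Nullable<Rcpp::List> covs0 = R_NilValue) {
  const arma::uword n = X.n_rows, d = X.n_cols, k = means0.n_rows;
  if (n <= k) stop("need more cases than components");

  arma::vec w(k, arma::fill::value(1.0 / k));
  arma::mat means = means0;

  // pooled covariance for initialization and for empty-component resets
  arma::mat pooled = arma::cov(X, 1);  // ML normalization
  pooled.diag() += reg_covar;

  arma::cube covs;
  arma::mat dvars;
  if (cov_type == 1) {
    dvars = arma::repmat(pooled.diag().t(), k, 1);
  } else if (cov_type == 0) {
    covs = arma::cube(d, d, 1);
    covs.slice(0) = pooled;
  } else {
    covs = arma::cube(d, d, k);
    for (arma::uword j = 0; j < k; ++j) covs.slice(j) = pooled;
  }

  // warm start from a previous fit's full parameter set
  if (weights0.isNotNull()) {
    w = Rcpp::as<arma::vec>(weights0.get());
    if (w.n_elem != k) stop("weights0 length mismatch");
  }
  if (covs0.isNotNull()) {
    List cl(covs0.get());
    if (cov_type == 1) {
      dvars = Rcpp::as<arma::mat>(cl[0]);
    } else if (cov_type == 0) {
      covs.slice(0) = Rcpp::as<arma::mat>(cl[0]);
    } else {
      if ((arma::uword)cl.size() != k) stop("covs0 length mismatch");
      for (arma::uword j = 0; j < k; ++j)
        covs.slice(j) = Rcpp::as<arma::mat>(cl[j]);
    }
  }

  arma::mat resp(n, k);
  std::vector<double> trace;
  trace.reserve(max_iter);
  double ll = -arma::datum::inf;
  bool converged = false;
  int n_reinit = 0;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    arma::mat lp = weighted_log_prob(X, w, means, cov_type, covs, dvars);
    double ll_new = log_resp(lp, resp);
    trace.push_back(ll_new);
    if (iter > 0 && std::abs(ll_new - ll) / n < tol) {
      ll = ll_new;
      converged = true;
      break;
    }
    ll = ll_new;

    // M step
    arma::rowvec Nk = arma::sum(resp, 0);
    // empty components: re-seed from the worst-fit case
    arma::uvec empty = arma::find(Nk.t() < 1e-6);
    if (empty.n_elem > 0) {
      arma::vec m = arma::max(lp, 1);
      arma::vec lse = m + arma::log(arma::sum(arma::exp(lp.each_col() - m), 1));
      for (arma::uword e = 0; e < empty.n_elem; ++e) {
        arma::uword j = empty(e);
        arma::uword worst = lse.index_min();
        means.row(j) = X.row(worst);
        if (cov_type == 1) dvars.row(j) = pooled.diag().t();
        else if (cov_type == 2) covs.slice(j) = pooled;
        // give the component a single case's worth of weight
        resp.col(j).zeros();
        resp(worst, j) = 1.0;
        lse(worst) = arma::datum::inf;  // don't pick the same case twice
        ++n_reinit;
      }
      // renormalize responsibilities row-wise
      arma::vec rs = arma::sum(resp, 1);
      resp.each_col() /= rs;
      Nk = arma::sum(resp, 0);
    }

    w = Nk.t() / n;
    for (arma::uword j = 0; j < k; ++j)
      means.row(j) = (resp.col(j).t() * X) / Nk(j);

    if (cov_type == 2) {
      for (arma::uword j = 0; j < k; ++j) {
        arma::mat centred = X.each_row() - means.row(j);
        arma::mat wc = centred.each_col() % resp.col(j);
        arma::mat S = (wc.t() * centred) / Nk(j);
        S = 0.5 * (S + S.t());
        S.diag() += reg_covar;
        covs.slice(j) = S;
      }
    } else if (cov_type == 1) {
      arma::mat X2 = arma::square(X);
      for (arma::uword j = 0; j < k; ++j) {
        arma::rowvec ex2 = (resp.col(j).t() * X2) / Nk(j);
        arma::rowvec v = ex2 - arma::square(means.row(j));
        v.transform([reg_covar](double val) {
          return (val < 0.0 ? 0.0 : val) + reg_covar;
        });
        dvars.row(j) = v;
      }
    } else {  // tied
      arma::mat S(d, d, arma::fill::zeros);
      for (arma::uword j = 0; j < k; ++j) {
        arma::mat centred = X.each_row() - means.row(j);
        arma::mat wc = centred.each_col() % resp.col(j);
        S += wc.t() * centred;
      }
      S /= n;
      S = 0.5 * (S + S.t());
      S.diag() += reg_covar;
      covs.slice(0) = S;
    }
  }

  if (!converged && iter == max_iter) {
    // final E step so that resp / loglik match the returned parameters
    arma::mat lp = weighted_log_prob(X, w, means, cov_type, covs, dvars);
    ll = log_resp(lp, resp);
    trace.push_back(ll);
  }

  List covariances;
  if (cov_type == 0) {
    covariances = List::create(wrap(covs.slice(0)));
  } else if (cov_type == 1) {
    covariances = List::create(wrap(dvars));
  } else {
    covariances = List(k);
    for (arma::uword j = 0; j < k; ++j) covariances[j] = wrap(covs.slice(j));
  }

  return List::create(
      _["weights"] = w, _["means"] = means, _["covariances"] = covariances,
      _["loglik"] = ll, _["loglik_trace"] = trace, _["resp"] = resp,
      _["converged"] = converged, _["n_iter"] = (int)trace.size(),
      _["n_reinit"] = n_reinit);
}

// [[Rcpp::export(name = ".gmm_logprob_cpp")]]
List gmm_logprob_cpp(const arma::mat& X, const arma::vec& w,
                     const arma::mat& means, int cov_type, List covariances) {
  const arma::uword d = X.n_cols, k = means.n_rows;
  arma::cube covs;
  arma::mat dvars;
  if (cov_type == 1) {
    dvars = as<arma::mat>(covariances[0]);
  } else if (cov_type == 0) {
    covs = arma::cube(d, d, 1);
    covs.slice(0) = as<arma::mat>(covariances[0]);
  } else {
    covs = arma::cube(d, d, k);
    for (arma::uword j = 0; j < k; ++j)
      covs.slice(j) = as<arma::mat>(covariances[j]);
  }
  arma::mat lp = weighted_log_prob(X, w, means, cov_type, covs, dvars);
  arma::mat resp;
  double ll = log_resp(lp, resp);
  return List::create(_["loglik"] = ll, _["resp"] = resp,
                      _["log_prob"] = lp);
}
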