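#include <Rcpp.h>
#include <R_ext/Applic.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// NB random-intercept marginal log-likelihood by adaptive Gauss-Hermite
// quadrature, plus a self-contained L-BFGS-B fitter. The per-observation
// terms lgamma(y + 1/alpha) - lgamma(1/alpha) - lgamma(y + 1) + y log(alpha)
// do not depend on the random intercept, so they are cached per alpha; the
// subject posterior modes are warm-started across objective evaluations.
// ---------------------------------------------------------------------------

struct AgqData {
  int n, p, n_subj, K;
  std::vector<double> y, X, offset;       // X is n x p, column-major
  std::vector<std::vector<int>> idx;      // observation indices per subject
  std::vector<double> ghx, ghw;
  // per-evaluation scratch
  std::vector<double> eta_fix;            // X beta + offset
  std::vector<double> nbconst;            // cached alpha-dependent constants
  double cached_alpha;
  std::vector<double> bmode;              // warm-started subject modes
};

// sum over one subject of the eta/b-dependent part of the NB log-pmf plus
// the normal log-density of b
static double subj_h(const AgqData& d, const std::vector<int>& ix, double b,
                     double inva, double alpha, double sigma2b) {
  double h = -0.5 * b * b / sigma2b - 0.5 * std::log(2.0 * M_PI * sigma2b);
  for (int j : ix) {
    double eta = d.eta_fix[j] + b;
    if (eta > 500.0) eta = 500.0;
    h += d.nbconst[j] + d.y[j] * eta -
         (d.y[j] + inva) * std::log1p(alpha * std::exp(eta));
  }
  return h;
}

static double agq_loglik(AgqData& d, const double* beta, double alpha,
                         double sigma2b) {
  double inva = 1.0 / alpha;
  for (int i = 0; i < d.n; i++) {
    double e = d.offset[i];
    for (int k = 0; k < d.p; k++) e += d.X[k * d.n + i] * beta[k];
    d.eta_fix[i] = e;
  }
  if (alpha != d.cached_alpha) {
    double la = std::log(alpha);
    double lgi = R::lgammafn(inva);
    for (int i = 0; i < d.n; i++)
      d.nbconst[i] = R::lgammafn(d.y[i] + inva) - lgi -
                     R::lgammafn(d.y[i] + 1.0) + d.y[i] * la;
    d.cached_alpha = alpha;
  }
  if (sigma2b < 1e-10) {
    double ll = 0.0;
    for (int i = 0; i < d.n; i++) {
      double eta = d.eta_fix[i];
      if (eta > 500.0) eta = 500.0;
      ll += d.nbconst[i] + d.y[i] * eta -
            (d.y[i] + inva) * std::log1p(alpha * std::exp(eta));
    }
    return ll;
  }
  double total = 0.0;
  for (int s = 0; s < d.n_subj; s++) {
    const std::vector<int>& ix = d.idx[s];
    if (ix.empty()) continue;
    // Newton mode-finding; the penalized log-density is strictly concave in b
    double b = d.bmode[s];
    double hcur = subj_h(d, ix, b, inva, alpha, sigma2b);
    double curv = -1.0 / sigma2b;
    for (int it = 0; it < 100; it++) {
      double score = -b / sigma2b;
      curv = -1.0 / sigma2b;
      for (int j : ix) {
        double eta = d.eta_fix[j] + b;
        if (eta > 500.0) eta = 500.0;
        double mu = std::exp(eta);
        double c = alpha * mu / (1.0 + alpha * mu);
        score += d.y[j] - (d.y[j] + inva) * c;
        curv  -= (d.y[j] + inva) * c / (1.0 + alpha * mu);
      }
      double step = -score / curv;
      if (!std::isfinite(step)) break;
      double bnew = b + step;
      double hnew = subj_h(d, ix, bnew, inva, alpha, sigma2b);
      int halve = 0;
      while ((!std::isfinite(hnew) || hnew < hcur) && halve < 40) {
        step *= 0.5;
        bnew = b + step;
        hnew = subj_h(d, ix, bnew, inva, alpha, sigma2b);
        halve++;
      }
      if (!std::isfinite(hnew)) break;
      double moved = std::fabs(bnew - b);
      b = bnew;
      hcur = hnew;
      if (moved < 1e-13) break;
    }
    d.bmode[s] = b;
    double sd = 1.0 / std::sqrt(-curv);
    double acc = 0.0;
    for (int k = 0; k < d.K; k++) {
      double bk = b + M_SQRT2 * sd * d.ghx[k];
      double hk = subj_h(d, ix, bk, inva, alpha, sigma2b);
      acc += d.ghw[k] * std::exp(hk - hcur + d.ghx[k] * d.ghx[k]);
    }
    total += hcur + std::log(acc) + 0.5 * std::log(2.0) + std::log(sd);
  }
  return total;
}

static AgqData make_data(const NumericVector& y, const NumericMatrix& X,
                         const NumericVector& offset, const IntegerVector& subj,
                         int n_subj, const NumericVector& ghx,
                         const NumericVector& ghw) {
  AgqData d;
  d.n = y.size();
  d.p = X.ncol();
  d.n_subj = n_subj;
  d.K = ghx.size();
  d.y.assign(y.begin(), y.end());
  d.X.assign(X.begin(), X.end());
  d.offset.assign(offset.begin(), offset.end());
  d.idx.resize(n_subj);
  for (int i = 0; i < d.n; i++) d.idx[subj[i]].push_back(i);
  d.ghx.assign(ghx.begin(), ghx.end());
  d.ghw.assign(ghw.begin(), ghw.end());
  d.eta_fix.resize(d.n);
  d.nbconst.resize(d.n);
  d.cached_alpha = -1.0;
  d.bmode.assign(n_subj, 0.0);
  return d;
}

// Marginal AGQ log-likelihood at fixed parameters (1 node = Laplace;
// sigma2b below 1e-10 collapses to the plain NB GLM log-likelihood).
// [[Rcpp::export]]
double nbmm_agq_loglik_cpp(NumericVector y, NumericMatrix X, NumericVector offset,
                           IntegerVector subj, int n_subj, NumericVector beta,
                           double alpha, double sigma2b, NumericVector ghx,
                           NumericVector ghw) {
  AgqData d = make_data(y, X, offset, subj, n_subj, ghx, ghw);
  return agq_loglik(d, beta.begin(), alpha, sigma2b);
}

// objective for lbfgsb: par = (beta, log alpha, log sigma2b)
static double agq_negll(int m, double* par, void* ex) {
  AgqData* d = static_cast<AgqData*>(ex);
  double ll = agq_loglik(*d, par, std::exp(par[d->p]), std::exp(par[d->p + 1]));
  return std::isfinite(ll) ? -ll : 1e10;
}

static void agq_numgrad(int m, double* par, double* gr, void* ex) {
  std::vector<double> x(par, par + m);
  for (int k = 0; k < m; k++) {
    double h = 1e-5 * (1.0 + std::fabs(x[k]));
    double xk = x[k];
    x[k] = xk + h;
    double fp = agq_negll(m, x.data(), ex);
    x[k] = xk - h;
    double fm = agq_negll(m, x.data(), ex);
    x[k] = xk;
    gr[k] = (fp - fm) / (2.0 * h);
  }
}

// Box-constrained quasi-Newton maximization of the AGQ marginal likelihood
// over (beta, log alpha, log sigma2b), using R's own L-BFGS-B.
// [[Rcpp::export]]
List nbmm_agq_fit_cpp(NumericVector y, NumericMatrix X, NumericVector offset,
                      IntegerVector subj, int n_subj, NumericVector par0,
                      NumericVector lower, NumericVector upper,
                      NumericVector ghx, NumericVector ghw, int maxit) {
  AgqData d = make_data(y, X, offset, subj, n_subj, ghx, ghw);
  int m = par0.size();
  std::vector<double> par(par0.begin(), par0.end());
  std::vector<double> lo(lower.begin(), lower.end());
  std::vector<double> up(upper.begin(), upper.end());
  std::vector<int> nbd(m, 2);  // both bounds
  double fmin = 0.0;
  int fail = 0, fncount = 0, grcount = 0;
  char msg[256];
  lbfgsb(m, 5, par.data(), lo.data(), up.data(), nbd.data(), &fmin,
         agq_negll, agq_numgrad, &fail, &d, 1e7, 1e-8, &fncount, &grcount,
         maxit, msg, 0, 10);
  return List::create(_["par"] = NumericVector(par.begin(), par.end()),
                      _["value"] = fmin, _["convergence"] = fail,
                      _["fncount"] = fncount + (m * 2) * grcount,
                      _["message"] = std::string(msg));
}
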