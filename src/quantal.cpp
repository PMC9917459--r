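#include <Rcpp.h>
using namespace Rcpp;

// Solve (diag(w) + lambda * D2' D2) z = w .* y for a pentadiagonal system,
// where D2 is the second-difference operator. Banded LDL' factorisation.
static void penta_solve(const std::vector<double>& d0,
                        const std::vector<double>& d1,
                        const std::vector<double>& d2,
                        const std::vector<double>& b,
                        std::vector<double>& x) {
  int n = (int)d0.size();
  std::vector<double> D(n), L1(n, 0.0), L2(n, 0.0), z(n);
  for (int i = 0; i < n; ++i) {
    double di = d0[i];
    if (i >= 1) di -= L1[i - 1] * L1[i - 1] * D[i - 1];
    if (i >= 2) di -= L2[i - 2] * L2[i - 2] * D[i - 2];
    D[i] = di;
    if (i + 1 < n) {
      double e = d1[i];
      if (i >= 1) e -= L1[i - 1] * D[i - 1] * L2[i - 1];
      L1[i] = e / D[i];
    }
    if (i + 2 < n) L2[i] = d2[i] / D[i];
  }
  // forward substitution L z = b
  for (int i = 0; i < n; ++i) {
    double zi = b[i];
    if (i >= 1) zi -= L1[i - 1] * z[i - 1];
    if (i >= 2) zi -= L2[i - 2] * z[i - 2];
    z[i] = zi;
  }
  // back substitution L' x = D^-1 z
  for (int i = n - 1; i >= 0; --i) {
    double xi = z[i] / D[i];
    if (i + 1 < n) xi -= L1[i] * x[i + 1];
    if (i + 2 < n) xi -= L2[i] * x[i + 2];
    x[i] = xi;
  }
}

// Asymmetric least squares baseline (iteratively reweighted penalised LS).
// Second-difference penalty weight = lambda; points above the current baseline
// get weight p, points below get 1 - p.
// [[Rcpp::export]]
List als_baseline_cpp(NumericVector y, double lambda, double p, int maxit) {
  int n = y.size();
  std::vector<double> w(n, 1.0), z(n, 0.0), d0(n), d1(n), d2(n), b(n);
  // stencil of lambda * D2'D2 (pentadiagonal, symmetric)
  std::vector<double> pen0(n), pen1(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double c = 6.0;
    if (i == 0 || i == n - 1) c = 1.0;
    else if (i == 1 || i == n - 2) c = 5.0;
    if (n < 3) c = 0.0;
    pen0[i] = lambda * c;
  }
  for (int i = 0; i + 1 < n; ++i) {
    double c = -4.0;
    if (i == 0 || i + 1 == n - 1) c = -2.0;
    pen1[i] = lambda * c;
  }
  if (n == 2) pen1[0] = 0.0;
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    for (int i = 0; i < n; ++i) {
      d0[i] = w[i] + pen0[i];
      b[i] = w[i] * y[i];
    }
    for (int i = 0; i + 1 < n; ++i) d1[i] = pen1[i];
    for (int i = 0; i + 2 < n; ++i) d2[i] = lambda;
    penta_solve(d0, d1, d2, b, z);
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double wi = (y[i] > z[i]) ? p : (1.0 - p);
      if (wi != w[i]) ++changed;
      w[i] = wi;
    }
    if (changed == 0) { converged = true; ++it; break; }
  }
  return List::create(_["baseline"] = NumericVector(z.begin(), z.end()),
                      _["converged"] = converged,
                      _["iterations"] = it);
}

// Expected bin counts of a quantal Gaussian mixture. Component k (k >= 1) is a
// Gaussian centred at k*q; the k = 0 (failure) component is a point mass
// assigned to the first bin. widths_grow selects sigma_k = sigma * sqrt(k).
// [[Rcpp::export]]
NumericVector qmix_expected_cpp(NumericVector edges, NumericVector weights,
                                double q, double sigma, double scale,
                                bool widths_grow) {
  int nb = edges.size() - 1;
  int K = weights.size() - 1;
  NumericVector out(nb);
  out[0] += scale * weights[0];
  for (int k = 1; k <= K; ++k) {
    double mu = k * q;
    double s = widths_grow ? sigma * std::sqrt((double)k) : sigma;
    double plo = R::pnorm(edges[0], mu, s, 1, 0);
    for (int b = 0; b < nb; ++b) {
      double phi = R::pnorm(edges[b + 1], mu, s, 1, 0);
      out[b] += scale * weights[k] * (phi - plo);
      plo = phi;
    }
  }
  return out;
}

// Weighted least-squares objective on binned counts for the global quantal fit.
// par = (log q, log sigma, log scale, theta_1..theta_C) with theta the
// condition release parameter: logit(P_R) for the binomial model (model = 0),
// log(lambda) for the Poisson model (model = 1). counts is bins x conditions.
// Poisson-variance weights with floor 1.
// [[Rcpp::export]]
double qmix_objective_cpp(NumericVector par, int model, int n_sites,
                          NumericVector edges, NumericMatrix counts,
                          double pois_mass) {
  int nc = counts.ncol();
  int nb = counts.nrow();
  double q = std::exp(par[0]);
  double sigma = std::exp(par[1]);
  double scale = std::exp(par[2]);
  double obj = 0.0;
  for (int c = 0; c < nc; ++c) {
    NumericVector w;
    bool grow = false;
    if (model == 0) {
      double pr = 1.0 / (1.0 + std::exp(-par[3 + c]));
      w = NumericVector(n_sites + 1);
      for (int k = 0; k <= n_sites; ++k) w[k] = R::dbinom(k, n_sites, pr, 0);
    } else {
      double lam = std::exp(par[3 + c]);
      int K = 1;
      double cum = R::ppois(K, lam, 1, 0);
      while (cum < pois_mass && K < 50) { ++K; cum = R::ppois(K, lam, 1, 0); }
      w = NumericVector(K + 1);
      double tot = R::ppois(K, lam, 1, 0);
      for (int k = 0; k <= K; ++k) w[k] = R::dpois(k, lam, 0) / tot;
      grow = true;
    }
    NumericVector e = qmix_expected_cpp(edges, w, q, sigma, scale, grow);
    for (int b = 0; b < nb; ++b) {
      double den = e[b] > 1.0 ? e[b] : 1.0;
      double r = counts(b, c) - e[b];
      obj += r * r / den;
    }
  }
  return obj;
}
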