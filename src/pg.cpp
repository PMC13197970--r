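// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Polya-Gamma PG(1, z) sampler (Devroye alternating-series method), used for
// the conjugate data augmentation of Bernoulli-logit models: with
// omega_i ~ PG(1, eta_i), the conditional for the coefficients is Gaussian.
// Uses R's RNG so draws are reproducible under set.seed().

static const double TRUNC = 0.64;
static const double PISQ = M_PI * M_PI;

static double a_coef(int n, double x) {
  double K = (n + 0.5) * M_PI;
  if (x > TRUNC) return K * std::exp(-0.5 * K * K * x);
  double expnt = -1.5 * (std::log(0.5 * M_PI) + std::log(x)) + std::log(K) -
                 2.0 * (n + 0.5) * (n + 0.5) / x;
  return std::exp(expnt);
}

static double mass_texpon(double Z) {
  double t = TRUNC;
  double fz = 0.125 * PISQ + 0.5 * Z * Z;
  double b = std::sqrt(1.0 / t) * (t * Z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * Z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - Z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + Z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse-Gaussian(1/Z, 1) truncated to (0, TRUNC)
static double rtigauss(double Z) {
  Z = std::fabs(Z);
  double t = TRUNC, X = t + 1.0;
  if (Z < 1.0 / t) {
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double E1 = exp_rand(), E2 = exp_rand();
      while (E1 * E1 > 2.0 * E2 / t) { E1 = exp_rand(); E2 = exp_rand(); }
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      alpha = std::exp(-0.5 * Z * Z * X);
    }
  } else {
    double mu = 1.0 / Z;
    while (X > t) {
      double Y = norm_rand(); Y *= Y;
      double mu_Y = mu * Y;
      X = mu + 0.5 * mu * mu_Y - 0.5 * mu * std::sqrt(4.0 * mu_Y + mu_Y * mu_Y);
      if (unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// [[Rcpp::export]]
double rpg1_cpp(double z) {
  double Z = std::fabs(z) * 0.5;
  double fz = 0.125 * PISQ + 0.5 * Z * Z;
  while (true) {
    double X;
    if (unif_rand() < mass_texpon(Z)) X = TRUNC + exp_rand() / fz;
    else X = rtigauss(Z);
    double S = a_coef(0, X);
    double Y = unif_rand() * S;
    int n = 0;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X;
      } else {
        S += a_coef(n, X);
        if (Y > S) break;
      }
    }
  }
}

// Gibbs sampler for a Bernoulli-logit model with fixed effects X (prior
// N(0, prior_sd^2), independent) and optional facility random intercepts
// (fac in 0..F-1, or F = 0 for none) with u_f ~ N(0, sigma^2),
// sigma ~ half-Normal(sigma_scale). sigma updated by slice sampling.
// [[Rcpp::export]]
List pg_gibbs_cpp(arma::mat X, arma::ivec y, arma::ivec fac, int n_fac,
                  arma::vec prior_sd, double sigma_scale, int n_iter,
                  int n_warmup, arma::vec beta_init) {
  const int n = X.n_rows, p = X.n_cols, F = n_fac;
  const int q = p + F;
  arma::vec beta = beta_init;
  arma::vec u(F, arma::fill::zeros);
  double sigma = 0.5;
  arma::vec kappa(n);
  for (int i = 0; i < n; ++i) kappa[i] = y[i] - 0.5;

  arma::vec xk = X.t() * kappa;          // fixed part of the Gaussian mean vector
  arma::vec fk(F, arma::fill::zeros);    // kappa aggregated by facility
  for (int i = 0; i < n; ++i) if (F > 0) fk[fac[i]] += kappa[i];

  const int n_keep = n_iter - n_warmup;
  arma::mat draws_beta(n_keep, p);
  arma::mat draws_u(n_keep, std::max(F, 1));
  arma::vec draws_sigma(n_keep);

  arma::vec omega(n), eta(n);
  arma::mat prec(q, q);
  arma::vec bvec(q), sol(q), zdraw(q);

  for (int it = 0; it < n_iter; ++it) {
    // eta and omega
    eta = X * beta;
    if (F > 0) for (int i = 0; i < n; ++i) eta[i] += u[fac[i]];
    for (int i = 0; i < n; ++i) omega[i] = rpg1_cpp(eta[i]);

    // joint Gaussian update of (beta, u)
    prec.zeros();
    arma::mat Xw = X.each_col() % omega;      // n x p, BLAS-friendly
    prec.submat(0, 0, p - 1, p - 1) = X.t() * Xw;
    for (int a = 0; a < p; ++a) prec(a, a) += 1.0 / (prior_sd[a] * prior_sd[a]);
    if (F > 0) {
      // X' Omega Z_fac  and diag(Z' Omega Z)
      for (int i = 0; i < n; ++i) {
        int f = fac[i];
        for (int a = 0; a < p; ++a) prec(a, p + f) += Xw(i, a);
        prec(p + f, p + f) += omega[i];
      }
      for (int a = 0; a < p; ++a)
        for (int f = 0; f < F; ++f) prec(p + f, a) = prec(a, p + f);
      for (int f = 0; f < F; ++f) prec(p + f, p + f) += 1.0 / (sigma * sigma);
    }
    for (int a = 0; a < p; ++a) bvec[a] = xk[a];
    for (int f = 0; f < F; ++f) bvec[p + f] = fk[f];

    arma::mat L = arma::chol(prec, "lower");
    sol = arma::solve(arma::trimatl(L), bvec);
    arma::vec mu_q = arma::solve(arma::trimatu(L.t()), sol);
    for (int a = 0; a < q; ++a) zdraw[a] = norm_rand();
    arma::vec draw = mu_q + arma::solve(arma::trimatu(L.t()), zdraw);
    beta = draw.head(p);
    if (F > 0) u = draw.tail(F);

    // sigma | u : slice sample on log sigma
    if (F > 0) {
      double ssq = arma::dot(u, u);
      auto logpost = [&](double ls) {
        double s = std::exp(ls);
        return -F * ls - 0.5 * ssq / (s * s) -
               0.5 * s * s / (sigma_scale * sigma_scale) + ls; // + Jacobian
      };
      double ls0 = std::log(sigma);
      double ly = logpost(ls0) - exp_rand();
      double wstep = 0.5;
      double lo = ls0 - wstep * unif_rand(), hi = lo + wstep;
      int guard = 0;
      while (logpost(lo) > ly && ++guard < 50) lo -= wstep;
      guard = 0;
      while (logpost(hi) > ly && ++guard < 50) hi += wstep;
      double ls1;
      while (true) {
        ls1 = lo + unif_rand() * (hi - lo);
        if (logpost(ls1) > ly) break;
        if (ls1 < ls0) lo = ls1; else hi = ls1;
      }
      sigma = std::exp(ls1);
    }

    if (it >= n_warmup) {
      int r = it - n_warmup;
      draws_beta.row(r) = beta.t();
      if (F > 0) draws_u.row(r) = u.t();
      draws_sigma[r] = sigma;
    }
  }

  return List::create(_["beta"] = draws_beta, _["u"] = draws_u,
                      _["sigma"] = draws_sigma);
}
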