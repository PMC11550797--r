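// Polya-Gamma auxiliary-variable Gibbs sampler for Bayesian logistic
// regression under regularized-horseshoe and Laplace (lasso) priors.
//
// All randomness flows through R's RNG (norm_rand/unif_rand/exp_rand), so a
// single set.seed() in R makes every chain reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TRUNC = 0.64;

// Piecewise coefficients a_n(x) of the alternating-series representation of
// the Jacobi density underlying PG(1, z) (Polson, Scott & Windle 2013).
static double a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x > TRUNC)
    return M_PI * nph * std::exp(-nph * nph * M_PI * M_PI * x / 2.0);
  return M_PI * nph * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * nph * nph / x);
}

// P(IG(mu = 1/z, lambda = 1) <= t)
static double pigauss(double t, double z) {
  double a = 1.0 / std::sqrt(t);
  double b = t * z;
  return R::pnorm(a * (b - 1.0), 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(-a * (b + 1.0), 0.0, 1.0, 1, 0);
}

// Inverse-Gaussian(1/z, 1) truncated to (0, TRUNC]
static double rtigauss(double z) {
  double t = TRUNC;
  double x = t + 1.0;
  double mu = (z > 0.0) ? 1.0 / z : R_PosInf;
  if (mu > t) {
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    while (x > t) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// One PG(1, z) draw by Devroye's alternating-series rejection sampler.
static double rpg1(double z) {
  z = 0.5 * std::fabs(z);
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double p = (M_PI / (2.0 * fz)) * std::exp(-fz * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  for (;;) {
    double x;
    if (unif_rand() < p / (p + q))
      x = TRUNC + exp_rand() / fz;
    else
      x = rtigauss(z);
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

//' @keywords internal
// [[Rcpp::export(rng = true)]]
NumericVector rpg_cpp(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

// Inverse-Gaussian(mu, lambda) (Michael, Schucany & Haas 1976)
static double rinvgauss1(double mu, double lambda) {
  double y = norm_rand();
  y = y * y;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = mu * mu / (mu + mu * mu * y / lambda);  // numeric guard
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Univariate slice sampler with stepping out (Neal 2003), on an unbounded
// coordinate (we always slice on the log of a positive scale).
template <class F>
static double slice1(F logf, double x0, double w, int m) {
  double fx0 = logf(x0);
  double logy = fx0 - exp_rand();
  double u = unif_rand() * w;
  double L = x0 - u;
  double R = x0 + (w - u);
  int j = (int)std::floor(unif_rand() * m);
  int k = m - 1 - j;
  while (j > 0 && logf(L) > logy) {
    L -= w;
    --j;
  }
  while (k > 0 && logf(R) > logy) {
    R += w;
    --k;
  }
  for (;;) {
    double x1 = L + unif_rand() * (R - L);
    if (logf(x1) > logy) return x1;
    if (x1 < x0)
      L = x1;
    else
      R = x1;
  }
}

// Draw (beta0, beta) | omega from the conjugate MVN given the PG augmentation.
// Returns the stacked coefficient vector; d holds the prior precisions of the
// p shrunk coefficients, prec0 the intercept prior precision.
static arma::vec draw_coef(const arma::mat& X, const arma::vec& kappa,
                           const arma::vec& omega, const arma::vec& d,
                           bool intercept, double prec0) {
  int p = X.n_cols;
  int q = intercept ? p + 1 : p;
  arma::mat prec(q, q);
  arma::vec b(q);
  arma::mat Xw = X.each_col() % omega;  // n x p: omega_i * x_ij
  if (intercept) {
    prec.submat(1, 1, q - 1, q - 1) = X.t() * Xw;
    arma::rowvec cross = arma::sum(Xw, 0);
    prec(0, 0) = arma::accu(omega) + prec0;
    prec.submat(0, 1, 0, q - 1) = cross;
    prec.submat(1, 0, q - 1, 0) = cross.t();
    for (int j = 0; j < p; ++j) prec(j + 1, j + 1) += d[j];
    b[0] = arma::accu(kappa);
    b.subvec(1, q - 1) = X.t() * kappa;
  } else {
    prec = X.t() * Xw;
    for (int j = 0; j < p; ++j) prec(j, j) += d[j];
    b = X.t() * kappa;
  }
  arma::mat U = arma::chol(prec);  // U'U = prec
  arma::vec tmp = arma::solve(arma::trimatl(U.t()), b);
  arma::vec mvec = arma::solve(arma::trimatu(U), tmp);
  arma::vec zvec(q);
  for (int i = 0; i < q; ++i) zvec[i] = norm_rand();
  return mvec + arma::solve(arma::trimatu(U), zvec);
}

// Regularized-horseshoe effective variance tau^2 * lambda_tilde_j^2
static inline double hs_var(double lam, double tau, double c2) {
  double tl = tau * lam;
  return c2 * tl * tl / (c2 + tl * tl);
}

//' @keywords internal
// [[Rcpp::export(rng = true)]]
List gibbs_horseshoe_cpp(const arma::mat& X, const arma::vec& y, double tau0,
                         double slab_scale, double slab_df, int n_warmup,
                         int n_draws, bool intercept, double intercept_sd,
                         bool fix_tau, double tau_value, bool fix_c2,
                         double c2_value) {
  int n = X.n_rows, p = X.n_cols;
  arma::vec kappa = y - 0.5;
  arma::vec beta(p, arma::fill::zeros);
  double beta0 = 0.0;
  arma::vec lambda(p, arma::fill::ones);
  double tau = fix_tau ? tau_value : tau0;
  double c2 = fix_c2 ? c2_value : slab_scale * slab_scale;
  double prec0 = 1.0 / (intercept_sd * intercept_sd);
  double nu = slab_df, s2 = slab_scale * slab_scale;

  arma::mat beta_draws(n_draws, p);
  arma::vec beta0_draws(n_draws);
  arma::mat lambda_draws(n_draws, p);
  arma::vec tau_draws(n_draws), c2_draws(n_draws);

  int total = n_warmup + n_draws;
  for (int it = 0; it < total; ++it) {
    // 1. Polya-Gamma augmentation
    arma::vec eta = X * beta;
    if (intercept) eta += beta0;
    arma::vec omega(n);
    for (int i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);

    // 2. (beta0, beta) | omega, scales
    arma::vec d(p);
    for (int j = 0; j < p; ++j) d[j] = 1.0 / hs_var(lambda[j], tau, c2);
    arma::vec coef = draw_coef(X, kappa, omega, d, intercept, prec0);
    if (intercept) {
      beta0 = coef[0];
      beta = coef.subvec(1, p);
    } else {
      beta = coef;
    }

    // 3. local scales lambda_j | beta_j, tau, c2  (slice on log lambda)
    for (int j = 0; j < p; ++j) {
      double bj = beta[j];
      auto logf = [&](double x) {
        double lam = std::exp(x);
        double v = hs_var(lam, tau, c2);
        return -std::log1p(lam * lam) + x - 0.5 * std::log(v) -
               bj * bj / (2.0 * v);
      };
      lambda[j] = std::exp(slice1(logf, std::log(lambda[j]), 1.0, 50));
    }

    // 4. global scale tau | beta, lambda, c2
    if (!fix_tau) {
      auto logf = [&](double x) {
        double t = std::exp(x);
        double r = t / tau0;
        double out = -std::log1p(r * r) + x;
        for (int j = 0; j < p; ++j) {
          double v = hs_var(lambda[j], t, c2);
          out += -0.5 * std::log(v) - beta[j] * beta[j] / (2.0 * v);
        }
        return out;
      };
      tau = std::exp(slice1(logf, std::log(tau), 1.0, 50));
    }

    // 5. slab width c^2 ~ Inv-Gamma(nu/2, nu s^2/2) a priori
    if (!fix_c2) {
      auto logf = [&](double x) {
        double c2x = std::exp(x);
        double out = -(nu / 2.0) * x - nu * s2 / (2.0 * c2x);
        for (int j = 0; j < p; ++j) {
          double v = hs_var(lambda[j], tau, c2x);
          out += -0.5 * std::log(v) - beta[j] * beta[j] / (2.0 * v);
        }
        return out;
      };
      c2 = std::exp(slice1(logf, std::log(c2), 1.0, 50));
    }

    if (it >= n_warmup) {
      int k = it - n_warmup;
      beta_draws.row(k) = beta.t();
      beta0_draws[k] = beta0;
      lambda_draws.row(k) = lambda.t();
      tau_draws[k] = tau;
      c2_draws[k] = c2;
    }
  }

  return List::create(
      Named("beta") = beta_draws, Named("beta0") = beta0_draws,
      Named("lambda") = lambda_draws, Named("tau") = tau_draws,
      Named("c2") = c2_draws);
}

//' @keywords internal
// [[Rcpp::export(rng = true)]]
List gibbs_laplace_cpp(const arma::mat& X, const arma::vec& y, double b_scale,
                       int n_warmup, int n_draws, bool intercept,
                       double intercept_sd) {
  int n = X.n_rows, p = X.n_cols;
  arma::vec kappa = y - 0.5;
  arma::vec beta(p, arma::fill::zeros);
  double beta0 = 0.0;
  arma::vec v(p, arma::fill::ones);  // mixture variances: beta_j ~ N(0, v_j)
  double prec0 = 1.0 / (intercept_sd * intercept_sd);
  double lam2 = 1.0 / (b_scale * b_scale);  // IG shape for 1/v_j

  arma::mat beta_draws(n_draws, p);
  arma::vec beta0_draws(n_draws);
  arma::mat v_draws(n_draws, p);

  int total = n_warmup + n_draws;
  for (int it = 0; it < total; ++it) {
    arma::vec eta = X * beta;
    if (intercept) eta += beta0;
    arma::vec omega(n);
    for (int i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);

    arma::vec d(p);
    for (int j = 0; j < p; ++j) d[j] = 1.0 / v[j];
    arma::vec coef = draw_coef(X, kappa, omega, d, intercept, prec0);
    if (intercept) {
      beta0 = coef[0];
      beta = coef.subvec(1, p);
    } else {
      beta = coef;
    }

    // 1/v_j | beta_j ~ Inverse-Gaussian(1/(b|beta_j|), 1/b^2)  (Park & Casella)
    for (int j = 0; j < p; ++j) {
      double ab = std::max(std::fabs(beta[j]), 1e-10);
      double inv = rinvgauss1(1.0 / (b_scale * ab), lam2);
      v[j] = 1.0 / std::max(inv, 1e-300);
    }

    if (it >= n_warmup) {
      int k = it - n_warmup;
      beta_draws.row(k) = beta.t();
      beta0_draws[k] = beta0;
      v_draws.row(k) = v.t();
    }
  }

  return List::create(Named("beta") = beta_draws,
                      Named("beta0") = beta0_draws, Named("v") = v_draws);
}
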