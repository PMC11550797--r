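#' Global scale of the regularized horseshoe prior
#'
#' Calibrates the prior scale of the global shrinkage parameter as the ratio
#' of the expected number of nonzero coefficients to the expected number of
#' zero coefficients, divided by the square root of the number of
#' observations: `tau0 = (p0 / (p - p0)) / sqrt(n)`.
#'
#' @param p0 Expected number of nonzero coefficients (0 < p0 < p).
#' @param p Total number of (shrunk) coefficients.
#' @param n Number of observations.
#' @return The global scale `tau0`.
#' @examples
#' compute_global_scale(p0 = 50, p = 100, n = 100) # 0.1
#' @export
compute_global_scale <- function(p0, p, n) {
  if (!(p0 > 0 && p0 < p)) abort("`p0` must satisfy 0 < p0 < p.")
  if (n < 1) abort("`n` must be at least 1.")
  (p0 / (p - p0)) / sqrt(n)
}

#' Slab scale of the regularized horseshoe prior
#'
#' Sets the slab scale as the square root of the ratio of a constant to the
#' expected number of nonzero coefficients, multiplied by the standard
#' deviation of the outcome: `s = sqrt(c0 / p0) * sd_y`. For a binary
#' outcome with prevalence q, `sd_y` is the population standard deviation
#' `sqrt(q * (1 - q))` (see [outcome_sd()]).
#'
#' @param c0 Positive slab constant.
#' @param p0 Expected number of nonzero coefficients.
#' @param sd_y Standard deviation of the outcome variable.
#' @return The slab scale `s`.
#' @examples
#' compute_slab_scale(c0 = 4, p0 = 1, sd_y = 0.5) # 1
#' @export
compute_slab_scale <- function(c0, p0, sd_y) {
  if (c0 <= 0 || p0 <= 0 || sd_y <= 0) {
    abort("`c0`, `p0` and `sd_y` must all be positive.")
  }
  sqrt(c0 / p0) * sd_y
}

#' Population standard deviation of a binary outcome
#'
#' @param y Binary (0/1) outcome vector.
#' @return `sqrt(mean(y) * (1 - mean(y)))`.
#' @export
outcome_sd <- function(y) {
  q <- mean(y)
  sqrt(q * (1 - q))
}

#' Regularized horseshoe prior
#'
#' The global-local shrinkage prior placed on the drug and covariate
#' coefficients: `beta_j ~ N(0, tau^2 * lambda_tilde_j^2)` with local scales
#' `lambda_j ~ half-Cauchy(0, 1)`, global scale `tau ~ half-Cauchy(0, tau0)`,
#' and slab regularization
#' `lambda_tilde_j^2 = c^2 lambda_j^2 / (c^2 + tau^2 lambda_j^2)`,
#' `c^2 ~ Inv-Gamma(nu/2, nu s^2/2)`. The hyperparameters `tau0` and `s` are
#' calibrated by [compute_global_scale()] and [compute_slab_scale()] at fit
#' time from the data dimensions unless given explicitly.
#'
#' @param p0 Expected number of nonzero coefficients. If `NULL`, a default
#'   of 5 is used and announced loudly, since this sparsity guess is the one
#'   hyperparameter the analyst should set deliberately.
#' @param global_scale Optional explicit `tau0` (overrides the formula).
#' @param slab_scale Optional explicit slab scale `s` (overrides the
#'   formula).
#' @param slab_df Slab degrees of freedom `nu` (default 4).
#' @param slab_constant The constant `c0` in the slab-scale formula; the
#'   default 31.25 makes `s = 2.5 * sd(y)` at the default `p0 = 5`.
#' @return An object of class `horseshoe_prior`.
#' @examples
#' horseshoe_prior(p0 = 5)
#' @export
horseshoe_prior <- function(p0 = NULL, global_scale = NULL,
                            slab_scale = NULL, slab_df = 4,
                            slab_constant = 31.25) {
  if (is.null(p0)) {
    p0 <- 5
    inform(paste(
      "horseshoe_prior(): `p0` (expected number of nonzero coefficients)",
      "was not set; defaulting to p0 = 5. Set it deliberately for your",
      "problem."
    ))
  }
  stopifnot(p0 > 0, slab_df > 0, slab_constant > 0)
  structure(
    list(
      p0 = p0, global_scale = global_scale, slab_scale = slab_scale,
      slab_df = slab_df, slab_constant = slab_constant
    ),
    class = c("horseshoe_prior", "adr_prior")
  )
}

#' Laplace (Bayesian lasso) prior
#'
#' Double-exponential prior `beta_j ~ Laplace(0, b)` on the shrunk
#' coefficients, the Bayesian analogue of L1 penalization.
#'
#' @param scale The scale `b > 0` (default 1).
#' @return An object of class `laplace_prior`.
#' @examples
#' laplace_prior(scale = 1)
#' @export
laplace_prior <- function(scale = 1) {
  stopifnot(scale > 0)
  structure(
    list(scale = scale),
    class = c("laplace_prior", "adr_prior")
  )
}

# Fill in tau0 / slab scale from the data dimensions (horseshoe only).
resolve_prior <- function(prior, p, n, sd_y) {
  if (inherits(prior, "horseshoe_prior")) {
    if (prior$p0 >= p) {
      abort("`p0` must be smaller than the number of predictors.")
    }
    prior$global_scale <- prior$global_scale %||%
      compute_global_scale(prior$p0, p, n)
    prior$slab_scale <- prior$slab_scale %||%
      compute_slab_scale(prior$slab_constant, prior$p0, sd_y)
  }
  prior
}

#' Draw from the prior hierarchy
#'
#' Exact ancestral sampling of the coefficient prior: for the regularized
#' horseshoe, `lambda_j`, `tau` and `c^2` are drawn from their hyperpriors
#' and `beta_j | lambda_j, tau, c` from the conditional normal; for the
#' Laplace prior, coefficients are drawn directly from the
#' double-exponential.
#'
#' @param prior A [horseshoe_prior()] (with explicit `global_scale` and
#'   `slab_scale`) or [laplace_prior()].
#' @param p Number of coefficients per draw.
#' @param n_draws Number of prior draws.
#' @param seed Integer seed.
#' @return A list of draw matrices (`n_draws` x `p` for `beta` and
#'   `lambda`; length-`n_draws` vectors for `tau` and `c2`). Laplace priors
#'   return only `beta`.
#' @examples
#' pr <- horseshoe_prior(p0 = 5, global_scale = 0.01, slab_scale = 1)
#' draws <- prior_predictive(pr, p = 3, n_draws = 100, seed = 1)
#' dim(draws$beta)
#' @export
prior_predictive <- function(prior, p, n_draws, seed = 1L) {
  stopifnot(n_draws >= 1)
  local_seed(seed, {
    if (inherits(prior, "laplace_prior")) {
      beta <- matrix(
        prior$scale * (rexp(n_draws * p) - rexp(n_draws * p)),
        n_draws, p
      )
      return(list(beta = beta))
    }
    if (is.null(prior$global_scale) || is.null(prior$slab_scale)) {
      abort(paste(
        "prior_predictive() needs explicit `global_scale` and `slab_scale`",
        "(they are data-calibrated at fit time)."
      ))
    }
    lambda <- matrix(abs(tan(pi * runif(n_draws * p) / 2)), n_draws, p)
    tau <- prior$global_scale * abs(tan(pi * runif(n_draws) / 2))
    c2 <- (prior$slab_df * prior$slab_scale^2 / 2) /
      rgamma(n_draws, shape = prior$slab_df / 2)
    lt2 <- c2 * (tau * lambda)^2 / (c2 + (tau * lambda)^2)
    beta <- matrix(rnorm(n_draws * p, sd = sqrt(lt2)), n_draws, p)
    list(beta = beta, lambda = lambda, tau = tau, c2 = c2)
  })
}

#' Unnormalized log posterior of the shrinkage logistic model
#'
#' Bernoulli log-likelihood of the logistic model plus all log prior
#' densities, up to an additive constant that does not depend on the
#' parameters. Serves as an engine-independent statement of the target
#' distribution the Gibbs sampler must leave invariant.
#'
#' @param X Predictor matrix (n x p), without intercept column.
#' @param y Binary outcome vector.
#' @param point Named list of parameter values: `beta0`, `beta`, and for the
#'   horseshoe `lambda`, `tau`, `c2` (all latents strictly positive).
#' @param prior A resolved [horseshoe_prior()] (explicit scales) or
#'   [laplace_prior()].
#' @param intercept_sd Prior standard deviation of the intercept.
#' @return The unnormalized log posterior density.
#' @export
log_unnorm_posterior <- function(X, y, point, prior, intercept_sd = 10) {
  X <- as.matrix(X)
  eta <- drop(X %*% point$beta) + point$beta0
  ll <- sum(stats::dbinom(y, 1, plogis(eta), log = TRUE))
  lp <- stats::dnorm(point$beta0, 0, intercept_sd, log = TRUE)
  if (inherits(prior, "laplace_prior")) {
    b <- prior$scale
    lp <- lp + sum(-log(2 * b) - abs(point$beta) / b)
  } else {
    lambda <- point$lambda
    tau <- point$tau
    c2 <- point$c2
    if (any(lambda <= 0) || tau <= 0 || c2 <= 0) {
      abort("All shrinkage latents must be strictly positive.")
    }
    lt2 <- c2 * (tau * lambda)^2 / (c2 + (tau * lambda)^2)
    lp <- lp + sum(stats::dnorm(point$beta, 0, sqrt(lt2), log = TRUE))
    lp <- lp + sum(log(2 / pi) - log1p(lambda^2)) # half-Cauchy(0,1)
    t0 <- prior$global_scale
    lp <- lp + log(2 / pi) - log(t0) - log1p((tau / t0)^2)
    nu <- prior$slab_df
    s2 <- prior$slab_scale^2
    a <- nu / 2
    b_ig <- nu * s2 / 2
    lp <- lp + a * log(b_ig) - lgamma(a) - (a + 1) * log(c2) - b_ig / c2
  }
  ll + lp
}
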