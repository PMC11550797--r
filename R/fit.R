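#' MCMC settings for the shrinkage fit
#'
#' @param n_chains Number of chains (default 4), run sequentially with
#'   deterministically derived per-chain seeds.
#' @param n_warmup,n_draws Warmup iterations discarded and post-warmup draws
#'   kept, per chain.
#' @param seed Master seed; chain c uses a seed derived from it.
#' @param rhat_max,ess_min Convergence thresholds: the fit is flagged (and a
#'   warning raised) when any monitored parameter has split-R-hat above
#'   `rhat_max` or effective sample size below `ess_min`.
#' @param include_intercept Include an intercept with a wide normal prior
#'   (sd `intercept_sd`), excluded from shrinkage.
#' @param intercept_sd Prior standard deviation of the intercept.
#' @param fix_tau,fix_c2 Optional fixed values for the horseshoe global
#'   scale and slab width (used mainly for validation against quadrature
#'   oracles); `NULL` samples them.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_chains = 4L, n_warmup = 1000L, n_draws = 1000L,
                       seed = 1L, rhat_max = 1.01, ess_min = 400L,
                       include_intercept = TRUE, intercept_sd = 10,
                       fix_tau = NULL, fix_c2 = NULL) {
  stopifnot(n_chains >= 1, n_warmup >= 0, n_draws >= 1, intercept_sd > 0)
  structure(
    list(
      n_chains = as.integer(n_chains),
      n_warmup = as.integer(n_warmup),
      n_draws = as.integer(n_draws),
      seed = as.integer(seed),
      rhat_max = rhat_max,
      ess_min = ess_min,
      include_intercept = isTRUE(include_intercept),
      intercept_sd = intercept_sd,
      fix_tau = fix_tau,
      fix_c2 = fix_c2
    ),
    class = "fit_config"
  )
}

#' Fit a sparse Bayesian logistic regression
#'
#' Fits `y ~ Bernoulli(plogis(beta0 + X beta))` with either the regularized
#' horseshoe or the Laplace (Bayesian lasso) prior on `beta`, using a
#' Polya-Gamma auxiliary-variable Gibbs sampler: conjugate multivariate-
#' normal updates for the coefficients given the augmentation, slice-sampling
#' updates for the horseshoe local/global scales and slab width, and
#' conjugate inverse-Gaussian updates for the Laplace mixture variances.
#'
#' @param data A data frame whose columns are the predictors plus the
#'   outcome; a `case_id` column, if present, is ignored as a predictor.
#'   Predictors are entered as-is (binary indicators, counts, age in years);
#'   no standardization is applied.
#' @param prior A [horseshoe_prior()] or [laplace_prior()].
#' @param outcome Name of the binary outcome column (default `"outcome"`).
#' @param config A [fit_config()].
#' @return An object of class `adr_fit`: posterior draw arrays
#'   (`draws[iteration, chain, parameter]` for intercept and coefficients;
#'   `shrinkage` holds the local scales and, for the horseshoe, `tau` and
#'   `c2` draws), the resolved prior, per-parameter convergence diagnostics,
#'   and a `converged` flag.
#' @examples
#' d <- tibble::tibble(
#'   x1 = rbinom(80, 1, 0.4), x2 = rbinom(80, 1, 0.3),
#'   outcome = rbinom(80, 1, 0.3)
#' )
#' fit <- fit_shrinkage(d, laplace_prior(),
#'   config = fit_config(n_chains = 2, n_warmup = 50, n_draws = 50)
#' )
#' tidy(fit)
#' @export
fit_shrinkage <- function(data, prior, outcome = "outcome",
                          config = fit_config()) {
  if (!outcome %in% names(data)) {
    abort(paste0("Outcome column `", outcome, "` not found in `data`."))
  }
  y <- as.numeric(data[[outcome]])
  if (!all(y %in% c(0, 1))) abort("Outcome must be binary 0/1.")
  pred_names <- setdiff(names(data), c(outcome, "case_id"))
  if (length(pred_names) == 0) abort("No predictor columns in `data`.")
  X <- as.matrix(data[pred_names])
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) abort("Predictor/outcome dimension mismatch.")
  n <- nrow(X)
  p <- ncol(X)

  sd_y <- outcome_sd(y)
  prior <- resolve_prior(prior, p = p, n = n, sd_y = sd_y)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chain_seed <- derive_seed(config$seed, 100L + ch)
    chains[[ch]] <- local_seed(chain_seed, {
      if (inherits(prior, "horseshoe_prior")) {
        gibbs_horseshoe_cpp(
          X, y,
          tau0 = prior$global_scale,
          slab_scale = prior$slab_scale,
          slab_df = prior$slab_df,
          n_warmup = config$n_warmup,
          n_draws = config$n_draws,
          intercept = config$include_intercept,
          intercept_sd = config$intercept_sd,
          fix_tau = !is.null(config$fix_tau),
          tau_value = config$fix_tau %||% 0,
          fix_c2 = !is.null(config$fix_c2),
          c2_value = config$fix_c2 %||% 0
        )
      } else {
        gibbs_laplace_cpp(
          X, y,
          b_scale = prior$scale,
          n_warmup = config$n_warmup,
          n_draws = config$n_draws,
          intercept = config$include_intercept,
          intercept_sd = config$intercept_sd
        )
      }
    })
  }

  par_names <- c(
    if (config$include_intercept) "(Intercept)",
    pred_names
  )
  n_par <- length(par_names)
  draws <- array(
    NA_real_,
    dim = c(config$n_draws, config$n_chains, n_par),
    dimnames = list(NULL, NULL, par_names)
  )
  for (ch in seq_len(config$n_chains)) {
    if (config$include_intercept) {
      draws[, ch, 1] <- chains[[ch]]$beta0
      draws[, ch, -1] <- chains[[ch]]$beta
    } else {
      draws[, ch, ] <- chains[[ch]]$beta
    }
  }
  shrinkage <- if (inherits(prior, "horseshoe_prior")) {
    list(
      lambda = lapply(chains, `[[`, "lambda"),
      tau = vapply(chains, `[[`, numeric(config$n_draws), "tau"),
      c2 = vapply(chains, `[[`, numeric(config$n_draws), "c2")
    )
  } else {
    list(v = lapply(chains, `[[`, "v"))
  }

  diagnostics <- tibble::tibble(
    term = par_names,
    rhat = vapply(
      seq_len(n_par), function(j) split_rhat(draws[, , j, drop = FALSE]),
      numeric(1)
    ),
    ess = vapply(
      seq_len(n_par), function(j) ess_mean(draws[, , j, drop = FALSE]),
      numeric(1)
    )
  )
  converged <- max(diagnostics$rhat, na.rm = TRUE) <= config$rhat_max &&
    min(diagnostics$ess, na.rm = TRUE) >= config$ess_min
  fit <- structure(
    list(
      draws = draws,
      shrinkage = shrinkage,
      prior = prior,
      config = config,
      terms = pred_names,
      n = n,
      p = p,
      sd_y = sd_y,
      outcome = outcome,
      diagnostics = diagnostics,
      converged = converged
    ),
    class = "adr_fit"
  )
  if (!converged) {
    warn(paste0(
      "Convergence diagnostics flagged: max R-hat = ",
      signif(max(diagnostics$rhat, na.rm = TRUE), 4),
      ", min ESS = ", round(min(diagnostics$ess, na.rm = TRUE)),
      " (thresholds ", config$rhat_max, " / ", config$ess_min,
      "). Increase warmup/draws."
    ))
  }
  fit
}

# Pooled posterior draws (iterations x chains collapsed) for one parameter.
pooled_draws <- function(fit, term) {
  as.vector(fit$draws[, , term])
}

#' @export
print.adr_fit <- function(x, ...) {
  prior_lab <- if (inherits(x$prior, "horseshoe_prior")) {
    sprintf(
      "regularized horseshoe (p0 = %g, tau0 = %.4g, slab scale = %.4g, nu = %g)",
      x$prior$p0, x$prior$global_scale, x$prior$slab_scale, x$prior$slab_df
    )
  } else {
    sprintf("Laplace (scale = %g)", x$prior$scale)
  }
  cat("Sparse Bayesian logistic regression\n")
  cat(sprintf("  prior: %s\n", prior_lab))
  cat(sprintf(
    "  n = %d, p = %d, chains = %d, draws/chain = %d\n",
    x$n, x$p, x$config$n_chains, x$config$n_draws
  ))
  cat(sprintf(
    "  max R-hat = %.3f, min ESS = %d, converged: %s\n",
    max(x$diagnostics$rhat, na.rm = TRUE),
    round(min(x$diagnostics$ess, na.rm = TRUE)),
    x$converged
  ))
  invisible(x)
}

#' Tidy posterior coefficient summaries
#'
#' One row per model term with the posterior median, equal-tailed 50% and
#' 90% credible intervals, convergence diagnostics, and the term's role
#' (`"drug"`, `"covariate"`, or `"intercept"`).
#'
#' @param x An `adr_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `role`, `estimate`, `ci50_lo`,
#'   `ci50_hi`, `ci90_lo`, `ci90_hi`, `rhat`, `ess`.
#' @export
tidy.adr_fit <- function(x, ...) {
  terms <- dimnames(x$draws)[[3]]
  summ <- purrr::map_dfr(terms, function(tm) {
    d <- pooled_draws(x, tm)
    ci50 <- credible_interval(d, 0.5)
    ci90 <- credible_interval(d, 0.9)
    tibble::tibble(
      term = tm,
      estimate = median(d),
      ci50_lo = ci50[1], ci50_hi = ci50[2],
      ci90_lo = ci90[1], ci90_hi = ci90[2]
    )
  })
  summ$role <- dplyr::case_when(
    summ$term == "(Intercept)" ~ "intercept",
    summ$term %in% covariate_names() ~ "covariate",
    TRUE ~ "drug"
  )
  dplyr::left_join(summ, x$diagnostics, by = "term") |>
    dplyr::select(
      "term", "role", "estimate",
      "ci50_lo", "ci50_hi", "ci90_lo", "ci90_hi", "rhat", "ess"
    )
}

#' One-line fit summary
#'
#' @param x An `adr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: data dimensions, prior family, chain/draw
#'   counts, worst-case diagnostics and the convergence flag.
#' @export
glance.adr_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    p = x$p,
    prior = class(x$prior)[1],
    n_chains = x$config$n_chains,
    n_draws = x$config$n_draws,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    converged = x$converged
  )
}
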