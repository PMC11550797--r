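# Shared test helpers: hand-built cohorts, an independent log-posterior
# implementation, the grid-quadrature oracle, and the frozen
# parameter-recovery benchmark.

# A cohort tibble from explicit drug lists (one case per list).
make_cohort <- function(drug_lists, visit_index = NULL, patient_id = NULL,
                        age = 70, sex = "male", outcome = 0L) {
  n <- length(drug_lists)
  tibble::tibble(
    case_id = sprintf("C%03d", seq_len(n)),
    patient_id = patient_id %||% sprintf("P%03d", seq_len(n)),
    visit_index = visit_index %||% rep(1L, n),
    age = rep_len(age, n),
    sex = rep_len(sex, n),
    drugs = drug_lists,
    outcome = rep_len(as.integer(outcome), n)
  )
}

# An all-false CYP table for the given drugs, with chosen flags set TRUE.
make_cyp_table <- function(drugs, ...) {
  flags <- adrsignal:::cyp_flag_names()
  tab <- tibble::as_tibble(
    c(
      list(drug_name = drugs),
      setNames(
        replicate(length(flags), rep(FALSE, length(drugs)), simplify = FALSE),
        flags
      )
    )
  )
  set <- list(...) # e.g. drugX = c("cyp3a4_substrate")
  for (d in names(set)) {
    for (f in set[[d]]) tab[tab$drug_name == d, f] <- TRUE
  }
  tab
}

# Independent re-implementation of the unnormalized log posterior, written
# with different building blocks (dcauchy / dgamma on the precision scale)
# than the package version.
reference_log_posterior <- function(X, y, point, prior, intercept_sd = 10) {
  eta <- drop(as.matrix(X) %*% point$beta) + point$beta0
  ll <- sum(y * eta - log1p(exp(eta)))
  lp <- dnorm(point$beta0, 0, intercept_sd, log = TRUE)
  if (inherits(prior, "laplace_prior")) {
    b <- prior$scale
    lp <- lp + sum(log(0.5 / b) - abs(point$beta) / b)
  } else {
    lam <- point$lambda
    tau <- point$tau
    c2 <- point$c2
    lt <- sqrt(c2 * (tau * lam)^2 / (c2 + (tau * lam)^2))
    lp <- lp + sum(dnorm(point$beta, 0, lt, log = TRUE))
    lp <- lp + sum(log(2) + dcauchy(lam, 0, 1, log = TRUE))
    lp <- lp + log(2) + dcauchy(tau, 0, prior$global_scale, log = TRUE)
    # c2 ~ Inv-Gamma(nu/2, nu s^2/2) via the gamma density of 1/c2
    nu <- prior$slab_df
    s2 <- prior$slab_scale^2
    lp <- lp + dgamma(1 / c2, shape = nu / 2, rate = nu * s2 / 2, log = TRUE) -
      2 * log(c2)
  }
  ll + lp
}

# 2-D grid-quadrature posterior moments for the 1-predictor regularized
# horseshoe logistic model with tau and c2 held fixed, no intercept.
# Marginalizes the local scale through the substitution u = (2/pi) atan(lambda)
# (uniform under the half-Cauchy prior).
quadrature_posterior_moments <- function(x, y, tau_fix, c2_fix,
                                         n_lambda = 4000,
                                         beta_grid = seq(-4, 6, by = 0.002)) {
  u <- (seq_len(n_lambda) - 0.5) / n_lambda
  lam <- tan(pi * u / 2)
  v <- c2_fix * (tau_fix * lam)^2 / (c2_fix + (tau_fix * lam)^2)
  ll <- vapply(
    beta_grid,
    function(b) sum(dbinom(y, 1, plogis(b * x), log = TRUE)),
    numeric(1)
  )
  log_prior <- vapply(beta_grid, function(b) {
    dn <- dnorm(b, 0, sqrt(v), log = TRUE)
    m <- max(dn)
    m + log(mean(exp(dn - m)))
  }, numeric(1))
  lp <- ll + log_prior
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mean_ <- sum(w * beta_grid)
  sd_ <- sqrt(sum(w * beta_grid^2) - mean_^2)
  c(mean = mean_, sd = sd_)
}

# Frozen parameter-recovery benchmark: p = 100 drug indicators, n = 4000,
# five planted positive effects on drugs at observed frequency ranks
# (3, 8, 15, 25, 40). Returns per-prior detection and flag counts.
recovery_benchmark <- function(seed, n_chains = 2, n_warmup = 300,
                               n_draws = 400) {
  spec <- cohort_spec(
    n_cases = 4000, catalog_size = 100, zipf_exponent = 1.5,
    combination_fraction = 0, unspecific_fraction = 0,
    supplement_fraction = 0, seed = seed
  )
  catalog <- build_drug_catalog(spec)
  cohort <- sample_cohort(spec, catalog)
  cfg <- config_from_catalog(catalog, min_count = 1, top_n = 100)
  norm <- adrsignal:::normalize_cohort(cohort, cfg)
  freq <- sort(
    table(unlist(lapply(norm$drugs_normalized, unique))),
    decreasing = TRUE
  )
  planted <- names(freq)[c(3, 8, 15, 25, 40)]
  eff <- true_effects(
    intercept = -2.5,
    drug_effects = setNames(c(1.0, 1.2, 1.5, 1.8, 2.0), planted)
  )
  cohort <- assign_outcomes(cohort, eff, cfg, seed = seed + 1)
  des <- curate_cohort(cohort, cfg)$design
  des <- dplyr::select(des, dplyr::all_of(c("case_id", names(freq), "outcome")))

  out <- list(planted = planted)
  for (pr in c("horseshoe", "lasso")) {
    prior <- if (pr == "horseshoe") {
      horseshoe_prior(p0 = 5)
    } else {
      laplace_prior(1)
    }
    fit <- suppressWarnings(suppressMessages(fit_shrinkage(
      des, prior,
      config = fit_config(
        n_chains = n_chains, n_warmup = n_warmup,
        n_draws = n_draws, seed = seed + 2
      )
    )))
    td <- tidy(fit)
    td <- td[td$role == "drug", ]
    cls <- setNames(
      classify_signal(td$ci50_lo, td$ci50_hi, td$ci90_lo, td$ci90_hi),
      td$term
    )
    is_pos <- cls %in% c("light_positive", "strong_positive")
    names(is_pos) <- names(cls)
    nulls <- setdiff(names(cls), planted)
    out[[pr]] <- list(
      planted_detected = sum(is_pos[planted]),
      nulls_none = sum(cls[nulls] == "none"),
      n_nulls = length(nulls),
      flags_50ci = sum(cls != "none")
    )
  }
  out
}
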