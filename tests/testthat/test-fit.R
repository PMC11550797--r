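test_that("fits are reproducible and validate their inputs", {
  set.seed(3)
  d <- tibble::tibble(
    x1 = rbinom(100, 1, 0.4), x2 = rbinom(100, 1, 0.2),
    outcome = rbinom(100, 1, 0.3)
  )
  cfg <- fit_config(
    n_chains = 2, n_warmup = 100, n_draws = 100, seed = 5, ess_min = 10,
    rhat_max = 2
  )
  f1 <- fit_shrinkage(d, horseshoe_prior(p0 = 1), config = cfg)
  f2 <- fit_shrinkage(d, horseshoe_prior(p0 = 1), config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$shrinkage$tau, f2$shrinkage$tau)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(nrow(tidy(f1)), 3) # intercept + 2 coefficients
  expect_equal(glance(f1)$p, 2)

  expect_error(
    fit_shrinkage(d, horseshoe_prior(p0 = 1), outcome = "missing"),
    "not found"
  )
  d_bad <- d
  d_bad$outcome <- d_bad$outcome + 1L
  expect_error(
    fit_shrinkage(d_bad, horseshoe_prior(p0 = 1), config = cfg),
    "binary"
  )
  expect_error(
    fit_shrinkage(d["outcome"], horseshoe_prior(p0 = 1), config = cfg),
    "predictor"
  )
})

test_that("an all-zero predictor column keeps its prior marginal", {
  set.seed(5)
  n <- 200
  d <- tibble::tibble(
    z1 = rep(0, n), z2 = rep(0, n),
    outcome = rbinom(n, 1, 0.3)
  )
  pr <- horseshoe_prior(p0 = 1, global_scale = 0.05, slab_scale = 1)
  fit <- suppressWarnings(fit_shrinkage(
    d, pr,
    config = fit_config(
      n_chains = 2, n_warmup = 300, n_draws = 2000, seed = 3, ess_min = 10,
      rhat_max = 10
    )
  ))
  post <- as.vector(fit$draws[, , "z1"])
  prior_draws <- prior_predictive(pr, p = 1, n_draws = 4000, seed = 9)$beta[, 1]
  ks <- suppressWarnings(ks.test(post, prior_draws))
  expect_gt(ks$p.value, 0.01)

  # same property under the Laplace prior, against the analytic CDF
  fl <- suppressWarnings(fit_shrinkage(
    d, laplace_prior(1),
    config = fit_config(
      n_chains = 2, n_warmup = 300, n_draws = 2000, seed = 4, ess_min = 10,
      rhat_max = 10
    )
  ))
  postl <- as.vector(fl$draws[, , "z1"])
  plap <- function(q) ifelse(q < 0, 0.5 * exp(q), 1 - 0.5 * exp(-q))
  expect_gt(suppressWarnings(ks.test(postl, plap))$p.value, 0.01)
})

test_that("permuting predictor columns permutes posterior summaries", {
  set.seed(8)
  n <- 300
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(-1 + 1.2 * x1 - 0.8 * x2))
  d_ab <- tibble::tibble(x1 = x1, x2 = x2, outcome = y)
  d_ba <- tibble::tibble(x2 = x2, x1 = x1, outcome = y)
  cfg <- fit_config(
    n_chains = 2, n_warmup = 300, n_draws = 1500, seed = 6, ess_min = 10,
    rhat_max = 10
  )
  t_ab <- tidy(suppressWarnings(
    fit_shrinkage(d_ab, horseshoe_prior(p0 = 1), config = cfg)
  ))
  t_ba <- tidy(suppressWarnings(
    fit_shrinkage(d_ba, horseshoe_prior(p0 = 1), config = cfg)
  ))
  for (tm in c("x1", "x2")) {
    expect_equal(
      t_ab$estimate[t_ab$term == tm], t_ba$estimate[t_ba$term == tm],
      tolerance = 0.08
    )
  }
})

test_that("under-iterated runs trip the diagnostics warning state", {
  set.seed(13)
  n <- 150
  x <- matrix(rbinom(n * 5, 1, 0.3), n, 5)
  d <- tibble::as_tibble(as.data.frame(x))
  d$outcome <- rbinom(n, 1, plogis(-1 + x[, 1]))
  expect_warning(
    fit <- fit_shrinkage(
      d, horseshoe_prior(p0 = 2),
      config = fit_config(n_chains = 2, n_warmup = 0, n_draws = 30, seed = 1)
    ),
    "diagnostics"
  )
  expect_false(fit$converged)
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))
})

test_that("a strong effect in moderate dimension is detected", {
  # p = 20, one true effect +1.5: its 90% CI excludes zero, a null's 50% CI
  # covers zero
  spec <- cohort_spec(
    n_cases = 1500, catalog_size = 20, combination_fraction = 0,
    unspecific_fraction = 0, supplement_fraction = 0, seed = 17
  )
  catalog <- build_drug_catalog(spec)
  cohort <- sample_cohort(spec, catalog)
  cfg <- config_from_catalog(catalog, min_count = 1, top_n = 20)
  norm <- adrsignal:::normalize_cohort(cohort, cfg)
  freq <- sort(
    table(unlist(lapply(norm$drugs_normalized, unique))),
    decreasing = TRUE
  )
  planted <- names(freq)[4]
  null_drug <- names(freq)[12]
  cohort <- assign_outcomes(
    cohort,
    true_effects(intercept = -2, drug_effects = setNames(1.5, planted)),
    cfg,
    seed = 18
  )
  des <- curate_cohort(cohort, cfg)$design
  des <- dplyr::select(des, dplyr::all_of(c(names(freq), "outcome")))
  fit <- suppressWarnings(suppressMessages(fit_shrinkage(
    des, horseshoe_prior(p0 = 2),
    config = fit_config(n_chains = 2, n_warmup = 300, n_draws = 500, seed = 19)
  )))
  td <- tidy(fit)
  expect_gt(td$ci90_lo[td$term == planted], 0)
  row_null <- td[td$term == null_drug, ]
  expect_true(row_null$ci50_lo <= 0 && row_null$ci50_hi >= 0)
})
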