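test_that("catalog generation honours size, flags and determinism", {
  # degenerate: one plain drug, no flags
  spec1 <- cohort_spec(
    n_cases = 10, catalog_size = 1, combination_fraction = 0,
    unspecific_fraction = 0, supplement_fraction = 0,
    cyp_substrate_prob = 0, cyp_inhibitor_prob = 0, seed = 1
  )
  cat1 <- build_drug_catalog(spec1)
  expect_equal(nrow(cat1), 1)
  expect_false(any(
    cat1$is_combination | cat1$is_unspecific | cat1$is_supplement
  ))
  expect_false(any(as.matrix(cat1[adrsignal:::cyp_flag_names()])))

  # seeded determinism
  spec2 <- cohort_spec(n_cases = 50, catalog_size = 200, seed = 42)
  expect_identical(build_drug_catalog(spec2), build_drug_catalog(spec2))

  # full-size catalog: all names distinct, flag fractions as configured
  spec3 <- cohort_spec(n_cases = 100, catalog_size = 1627, seed = 3)
  cat3 <- build_drug_catalog(spec3)
  expect_equal(nrow(cat3), 1627)
  expect_equal(length(unique(cat3$drug_name)), 1627)
  expect_equal(sum(cat3$is_combination), round(1627 * 0.05))
  expect_true(all(grepl("/", cat3$drug_name[cat3$is_combination])))

  expect_error(cohort_spec(n_cases = 10, catalog_size = 0), "catalog_size")
})

test_that("cohort sampling meets the count contracts", {
  spec <- cohort_spec(
    n_cases = 3, n_repeat_visits = 1, n_missing_medication = 0,
    catalog_size = 10, seed = 2
  )
  cohort <- sample_cohort(spec, build_drug_catalog(spec))
  expect_equal(nrow(cohort), 3)
  expect_equal(sum(cohort$visit_index == 2), 1)
  repeat_patient <- cohort$patient_id[cohort$visit_index == 2]
  expect_true(any(
    cohort$patient_id == repeat_patient & cohort$visit_index == 1
  ))

  spec2 <- cohort_spec(
    n_cases = 400, n_repeat_visits = 25, n_missing_medication = 3,
    catalog_size = 50, seed = 5
  )
  cohort2 <- sample_cohort(spec2, build_drug_catalog(spec2))
  expect_equal(nrow(cohort2), 400)
  expect_equal(sum(cohort2$visit_index == 2), 25)
  empty <- lengths(cohort2$drugs) == 0
  expect_equal(sum(empty), 3)
  expect_true(all(cohort2$visit_index[empty] == 1))
  # no duplicate drugs within a case
  expect_true(all(vapply(
    cohort2$drugs, function(d) !anyDuplicated(d), logical(1)
  )))
  expect_true(all(cohort2$age >= 18 & cohort2$age <= 105))

  expect_error(
    cohort_spec(n_cases = 3, n_repeat_visits = 2, n_missing_medication = 1),
    "n_cases"
  )
})

test_that("cohort sampling is byte-deterministic given the spec seed", {
  spec <- cohort_spec(n_cases = 120, catalog_size = 60, seed = 11)
  catalog <- build_drug_catalog(spec)
  expect_identical(
    sample_cohort(spec, catalog),
    sample_cohort(spec, catalog)
  )
})

test_that("drug popularity follows the configured Zipf curve", {
  spec <- cohort_spec(
    n_cases = 6000, catalog_size = 600, zipf_exponent = 1.5,
    combination_fraction = 0, unspecific_fraction = 0,
    supplement_fraction = 0, seed = 31
  )
  cohort <- sample_cohort(spec, build_drug_catalog(spec))
  freq <- sort(
    as.integer(table(unlist(cohort$drugs))),
    decreasing = TRUE
  )
  # rank curve monotone non-increasing by construction of sort; recover the
  # exponent by log-log regression over mid ranks (top ranks saturate because
  # drugs are sampled without replacement within a case)
  rng <- 10:200
  f <- freq[rng]
  slope <- -unname(coef(lm(log(f) ~ log(rng)))[2])
  expect_lt(abs(slope - 1.5) / 1.5, 0.2)
})

test_that("outcome generation follows the logistic ground-truth model", {
  spec <- cohort_spec(n_cases = 10000, catalog_size = 20, seed = 7)
  catalog <- build_drug_catalog(spec)
  cohort <- sample_cohort(spec, catalog)

  # intercept 0, no effects: prevalence 1/2 within 3 binomial SE
  c0 <- assign_outcomes(cohort, true_effects(intercept = 0), seed = 70)
  expect_lt(abs(mean(c0$outcome) - 0.5), 3 * sqrt(0.25 / 10000))

  # intercept log(455/6720): prevalence ~ 455/7175
  q <- 455 / 7175
  c1 <- assign_outcomes(
    cohort, true_effects(intercept = log(455 / 6720)),
    seed = 71
  )
  expect_lt(abs(mean(c1$outcome) - q), 3 * sqrt(q * (1 - q) / 10000))

  # a +3 drug effect separates exposed from unexposed by a large margin
  top_drug <- names(sort(table(unlist(cohort$drugs)), decreasing = TRUE))[1]
  c2 <- assign_outcomes(
    cohort,
    true_effects(intercept = -3, drug_effects = setNames(3, top_drug)),
    seed = 72
  )
  exposed <- vapply(c2$drugs, function(d) top_drug %in% d, logical(1))
  expect_gt(mean(c2$outcome[exposed]) - mean(c2$outcome[!exposed]), 0.2)

  # empirical prevalence tracks the mean true probability
  p_true <- attr(c2, "true_prob")
  se <- sqrt(sum(p_true * (1 - p_true))) / length(p_true)
  expect_lt(abs(mean(c2$outcome) - mean(p_true)), 3 * se)

  expect_error(
    assign_outcomes(
      cohort, true_effects(covariate_effects = c(bmi = 1)),
      seed = 73
    ),
    "Unknown covariate"
  )
})

test_that("cohort CSV round-trip preserves the cohort", {
  spec <- cohort_spec(
    n_cases = 60, n_missing_medication = 2, catalog_size = 30, seed = 8
  )
  catalog <- build_drug_catalog(spec)
  cohort <- sample_cohort(spec, catalog)
  cohort <- assign_outcomes(cohort, true_effects(intercept = -1), seed = 80)
  dir <- withr::local_tempdir()
  write_cohort_csv(cohort, dir, catalog = catalog)
  back <- read_cohort_csv(dir)
  expect_equal(back$cohort$case_id, cohort$case_id)
  expect_equal(back$cohort$outcome, cohort$outcome)
  # drug sets preserved (order within a case is not significant)
  expect_true(all(mapply(
    setequal, back$cohort$drugs, cohort$drugs
  )))
  expect_equal(back$catalog$drug_name, catalog$drug_name)
})
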