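#' Specify a synthetic polypharmacy cohort
#'
#' A `cohort_spec` collects every knob of the synthetic-cohort generator:
#' cohort size and visit structure, the size and skew of the drug catalog,
#' the distribution of drugs per case, and the demographic distributions.
#' Defaults are calibrated to emulate a large multi-centre emergency-department
#' adverse-drug-reaction cohort: a skewed drug-popularity curve with a long
#' tail, a median of about 7 drugs per case (IQR roughly 3--10), and a
#' left-skewed age distribution with median about 72 years (IQR roughly
#' 58--81).
#'
#' @param n_cases Number of case records (emergency-department presentations).
#' @param n_repeat_visits Number of cases that are a second visit of a patient
#'   already in the cohort. Each selected patient contributes exactly one
#'   extra visit (`visit_index = 2`).
#' @param n_missing_medication Number of first-visit cases whose medication
#'   list is empty (missing medication record).
#' @param catalog_size Number of distinct substances in the drug catalog.
#' @param zipf_exponent Exponent of the Zipf popularity weights
#'   (weight of rank r is proportional to `r^-zipf_exponent`); larger values
#'   concentrate exposure on fewer drugs.
#' @param drugs_per_case_mean,drugs_per_case_dispersion Mean and dispersion
#'   (size) of the negative-binomial number of drugs per case, truncated to
#'   at least 1.
#' @param age_location,age_scale,age_skew Location, scale and shape of the
#'   skew-normal age distribution, truncated to \[18, 105\] years.
#' @param female_fraction Proportion of female patients.
#' @param combination_fraction,unspecific_fraction,supplement_fraction
#'   Fractions of catalog entries that are combination products ("a/b"
#'   names), unspecific drug names, and food supplements.
#' @param cyp_substrate_prob,cyp_inhibitor_prob Per-enzyme probability that a
#'   catalog drug is a substrate (resp. inhibitor) of each of CYP3A4, CYP2D6,
#'   CYP2C19 and CYP2C9; flags are assigned independently.
#' @param seed Integer seed; all generator randomness is derived from it.
#'
#' @return An object of class `cohort_spec` (a named list).
#' @examples
#' spec <- cohort_spec(n_cases = 500, catalog_size = 100, seed = 1)
#' spec$n_cases
#' @export
cohort_spec <- function(n_cases = 2000,
                        n_repeat_visits = 0,
                        n_missing_medication = 0,
                        catalog_size = 1627,
                        zipf_exponent = 1.5,
                        drugs_per_case_mean = 7.8,
                        drugs_per_case_dispersion = 2.5,
                        age_location = 91,
                        age_scale = 29,
                        age_skew = -5,
                        female_fraction = 0.492,
                        combination_fraction = 0.05,
                        unspecific_fraction = 0.02,
                        supplement_fraction = 0.03,
                        cyp_substrate_prob = 0.15,
                        cyp_inhibitor_prob = 0.08,
                        seed = 1L) {
  spec <- list(
    n_cases = as.integer(n_cases),
    n_repeat_visits = as.integer(n_repeat_visits),
    n_missing_medication = as.integer(n_missing_medication),
    catalog_size = as.integer(catalog_size),
    zipf_exponent = zipf_exponent,
    drugs_per_case_mean = drugs_per_case_mean,
    drugs_per_case_dispersion = drugs_per_case_dispersion,
    age_location = age_location,
    age_scale = age_scale,
    age_skew = age_skew,
    female_fraction = female_fraction,
    combination_fraction = combination_fraction,
    unspecific_fraction = unspecific_fraction,
    supplement_fraction = supplement_fraction,
    cyp_substrate_prob = cyp_substrate_prob,
    cyp_inhibitor_prob = cyp_inhibitor_prob,
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$catalog_size < 1L) {
    abort("`catalog_size` must be at least 1.")
  }
  if (spec$n_repeat_visits + spec$n_missing_medication >= spec$n_cases) {
    abort("`n_repeat_visits` + `n_missing_medication` must be < `n_cases`.")
  }
  if (spec$female_fraction < 0 || spec$female_fraction > 1) {
    abort("`female_fraction` must lie in [0, 1].")
  }
  stopifnot(
    spec$zipf_exponent > 0,
    spec$drugs_per_case_mean > 0,
    spec$drugs_per_case_dispersion > 0
  )
  invisible(spec)
}

#' Sparse ground-truth effects for outcome generation
#'
#' Defines the sparse logistic model from which synthetic outcomes are drawn:
#' an intercept (log-odds of the outcome for a zero row), a handful of nonzero
#' per-drug log-odds effects, and effects on the clinical covariates (age in
#' years, female sex, number of excluded drugs, and the eight CYP450
#' substrate/inhibitor counts).
#'
#' @param intercept Intercept on the log-odds scale.
#' @param drug_effects Named numeric vector of per-drug log-odds effects;
#'   names must be substances present in the catalog (after normalization).
#' @param covariate_effects Named numeric vector with any subset of names
#'   `age`, `sex_female`, `n_excluded`, `cyp3a4_substrates`,
#'   `cyp2d6_substrates`, `cyp2c19_substrates`, `cyp2c9_substrates`,
#'   `cyp3a4_inhibitors`, `cyp2d6_inhibitors`, `cyp2c19_inhibitors`,
#'   `cyp2c9_inhibitors`. Unlisted covariates have effect 0.
#'
#' @return An object of class `true_effects`.
#' @examples
#' true_effects(intercept = -3, drug_effects = c(drug0001 = 1.5))
#' @export
true_effects <- function(intercept = 0,
                         drug_effects = numeric(),
                         covariate_effects = numeric()) {
  known <- covariate_names()
  bad <- setdiff(names(covariate_effects), known)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown covariate effect(s): ", paste(bad, collapse = ", "),
      ". Known covariates: ", paste(known, collapse = ", "), "."
    ))
  }
  stopifnot(
    is.finite(intercept),
    all(is.finite(drug_effects)),
    all(is.finite(covariate_effects))
  )
  structure(
    list(
      intercept = intercept,
      drug_effects = drug_effects,
      covariate_effects = covariate_effects
    ),
    class = "true_effects"
  )
}

covariate_names <- function() {
  c(
    "age", "sex_female", "n_excluded",
    paste0(c("cyp3a4", "cyp2d6", "cyp2c19", "cyp2c9"), "_substrates"),
    paste0(c("cyp3a4", "cyp2d6", "cyp2c19", "cyp2c9"), "_inhibitors")
  )
}
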