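#' Sample a raw synthetic cohort
#'
#' Draws a cohort of emergency-department cases from a drug catalog. Each
#' patient gets one first visit; `n_repeat_visits` randomly chosen patients
#' additionally get a second visit. Drug counts per case are
#' negative-binomial (truncated to at least one drug), and drug identities
#' are drawn without replacement within a case from Zipf popularity weights
#' over the catalog. Exactly `n_missing_medication` first-visit cases have
#' an empty medication list. Outcomes are left `NA`; see
#' [assign_outcomes()].
#'
#' @param spec A [cohort_spec()].
#' @param catalog A drug catalog from [build_drug_catalog()].
#' @param seed Optional integer seed; defaults to a seed derived from
#'   `spec$seed`.
#'
#' @return A tibble with one row per case: `case_id`, `patient_id`,
#'   `visit_index`, `age`, `sex` (`"female"`/`"male"`), `drugs` (list column
#'   of character vectors), `outcome` (integer, `NA` until assigned).
#' @examples
#' spec <- cohort_spec(n_cases = 50, catalog_size = 30, seed = 1)
#' cohort <- sample_cohort(spec, build_drug_catalog(spec))
#' nrow(cohort)
#' @export
sample_cohort <- function(spec, catalog, seed = NULL) {
  validate_cohort_spec(spec)
  stopifnot(is.data.frame(catalog), "drug_name" %in% names(catalog))
  seed <- seed %||% derive_seed(spec$seed, 23L)
  local_seed(seed, {
    n_patients <- spec$n_cases - spec$n_repeat_visits
    width <- max(6L, nchar(as.character(spec$n_cases)))
    patient_id <- sprintf(paste0("P%0", width, "d"), seq_len(n_patients))
    age <- round(rskewnorm_trunc(
      n_patients, spec$age_location, spec$age_scale, spec$age_skew
    ))
    sex <- ifelse(runif(n_patients) < spec$female_fraction, "female", "male")

    repeat_patients <- if (spec$n_repeat_visits > 0) {
      sample(patient_id, spec$n_repeat_visits)
    } else {
      character(0)
    }
    cohort <- tibble::tibble(
      patient_id = c(patient_id, repeat_patients),
      visit_index = rep(
        c(1L, 2L), c(n_patients, length(repeat_patients))
      ),
      age = c(age, age[match(repeat_patients, patient_id)]),
      sex = c(sex, sex[match(repeat_patients, patient_id)])
    )
    cohort <- dplyr::arrange(cohort, .data$patient_id, .data$visit_index)
    cohort$case_id <- sprintf(
      paste0("C%0", width, "d"), seq_len(nrow(cohort))
    )

    n_drugs <- pmax(1L, rnbinom(
      nrow(cohort),
      mu = spec$drugs_per_case_mean,
      size = spec$drugs_per_case_dispersion
    ))
    n_drugs <- pmin(n_drugs, nrow(catalog))
    weights <- seq_len(nrow(catalog))^(-spec$zipf_exponent)
    cohort$drugs <- lapply(n_drugs, function(k) {
      sample(catalog$drug_name, k, prob = weights)
    })

    if (spec$n_missing_medication > 0) {
      first_idx <- which(cohort$visit_index == 1L)
      miss <- sample(first_idx, spec$n_missing_medication)
      cohort$drugs[miss] <- replicate(
        length(miss), character(0),
        simplify = FALSE
      )
    }
    cohort$outcome <- NA_integer_
    dplyr::select(
      cohort, "case_id", "patient_id", "visit_index",
      "age", "sex", "drugs", "outcome"
    )
  })
}

#' Assign outcomes from a sparse logistic ground-truth model
#'
#' Draws each case's binary outcome from
#' `Bernoulli(plogis(intercept + x %*% effects))`, where the predictors are
#' the case's normalized drug exposures and clinical covariates (age, female
#' sex, number of excluded drugs, CYP450 substrate/inhibitor counts) computed
#' with the curation module's annotators.
#'
#' Covariates with zero effect are skipped, so a pure drug-effect model does
#' not require a CYP table or drug selection.
#'
#' @param cohort A raw cohort tibble (see [sample_cohort()]).
#' @param effects A [true_effects()] object.
#' @param config A [curation_config()]; used to normalize drug names and,
#'   when `n_excluded` or CYP effects are nonzero, to compute those
#'   covariates.
#' @param seed Integer seed for the Bernoulli draws.
#'
#' @return The cohort with its `outcome` column filled in. The vector of true
#'   event probabilities is attached as attribute `"true_prob"`.
#' @examples
#' spec <- cohort_spec(n_cases = 100, catalog_size = 20, seed = 2)
#' cohort <- sample_cohort(spec, build_drug_catalog(spec))
#' cohort <- assign_outcomes(cohort, true_effects(intercept = -1), seed = 3)
#' mean(cohort$outcome)
#' @export
assign_outcomes <- function(cohort, effects,
                            config = curation_config(),
                            seed = 1L) {
  stopifnot(inherits(effects, "true_effects"))
  eta <- linear_predictor(cohort, effects, config)
  prob <- plogis(eta)
  local_seed(seed, {
    cohort$outcome <- rbinom(nrow(cohort), 1L, prob)
  })
  attr(cohort, "true_prob") <- prob
  cohort
}

# Per-case linear predictor under a true_effects model.
linear_predictor <- function(cohort, effects, config) {
  norm <- normalize_cohort(cohort, config)
  eta <- rep(effects$intercept, nrow(cohort))

  if (length(effects$drug_effects) > 0) {
    eta <- eta + vapply(norm$drugs_normalized, function(d) {
      sum(effects$drug_effects[names(effects$drug_effects) %in% d])
    }, numeric(1))
  }

  cov_eff <- effects$covariate_effects
  cov_eff <- cov_eff[cov_eff != 0]
  if (length(cov_eff) == 0) {
    return(eta)
  }
  if ("age" %in% names(cov_eff)) {
    eta <- eta + cov_eff[["age"]] * cohort$age
  }
  if ("sex_female" %in% names(cov_eff)) {
    eta <- eta + cov_eff[["sex_female"]] * as.numeric(cohort$sex == "female")
  }
  if ("n_excluded" %in% names(cov_eff)) {
    sel <- select_top_drugs(norm, config)
    n_not_sel <- vapply(norm$drugs_normalized, function(d) {
      sum(!d %in% sel$selected)
    }, numeric(1))
    eta <- eta + cov_eff[["n_excluded"]] * (n_not_sel + norm$n_dropped_norm)
  }
  cyp_eff <- intersect(names(cov_eff), paste0(cyp_flag_names(), "s"))
  if (length(cyp_eff) > 0) {
    counts <- annotate_cyp_cohort(norm, config$cyp_table)
    for (nm in cyp_eff) {
      eta <- eta + cov_eff[[nm]] * counts[[nm]]
    }
  }
  eta
}

#' A fixed benchmark cohort with exact data-flow counts
#'
#' Generates a deterministic-by-seed synthetic cohort sized like a large
#' multi-centre emergency-department ADR study: 7967 case records, of which
#' 791 are repeat visits and 1 has a missing medication record, over a
#' catalog of 1627 substances, so that first-visit filtering and
#' missing-medication exclusion leave exactly 7175 analysis cases. Outcome
#' labels are assigned so that, among those 7175 curation survivors, exactly
#' 455 cases are positive for the `"fall"` variant and exactly 1977 for the
#' `"bleeding"` variant; positives are drawn without replacement with
#' probability proportional to each case's odds under a planted sparse
#' ground-truth model (five nonzero drug effects plus age, female sex and
#' CYP2C19-substrate-count effects), so the planted signals are recoverable.
#'
#' @param seed Integer seed.
#' @param outcome `"fall"` or `"bleeding"`.
#'
#' @return A list with elements `cohort` (raw cohort tibble with outcomes),
#'   `catalog`, `effects` (the planted [true_effects()]), and `config` (a
#'   [curation_config()] wired to the catalog's unspecific/supplement names
#'   and CYP table).
#' @examples
#' \donttest{
#' fx <- fixture_cohort(seed = 1, outcome = "fall")
#' nrow(fx$cohort)
#' }
#' @export
fixture_cohort <- function(seed = 1L, outcome = c("fall", "bleeding")) {
  outcome <- match.arg(outcome)
  spec <- cohort_spec(
    n_cases = 7967L,
    n_repeat_visits = 791L,
    n_missing_medication = 1L,
    catalog_size = 1627L,
    seed = as.integer(seed)
  )
  catalog <- build_drug_catalog(spec)
  cohort <- sample_cohort(spec, catalog)
  config <- config_from_catalog(catalog)

  # survivors of the curation entry filters
  first <- keep_first_visits(cohort)
  surv <- drop_missing_medication(first)

  # plant effects on mid-popularity plain substances of the survivors
  norm <- normalize_cohort(surv, config)
  freq <- sort(table(unlist(lapply(norm$drugs_normalized, unique))),
    decreasing = TRUE
  )
  plain <- names(freq)[!grepl("/", names(freq))]
  planted <- plain[c(3, 6, 10, 15, 25)]
  n_pos <- if (outcome == "fall") 455L else 1977L
  prevalence <- n_pos / nrow(surv)
  effects <- true_effects(
    intercept = qlogis(prevalence) - 0.01 * 72,
    drug_effects = setNames(c(1.5, 1.2, 1.0, 0.8, 0.6), planted),
    covariate_effects = c(
      age = 0.01, sex_female = 0.2, cyp2c19_substrates = 0.2
    )
  )

  eta <- linear_predictor(surv, effects, config)
  local_seed(derive_seed(spec$seed, 37L), {
    pos_ids <- sample(surv$case_id, n_pos, prob = exp(eta))
    cohort$outcome <- ifelse(
      cohort$case_id %in% surv$case_id,
      as.integer(cohort$case_id %in% pos_ids),
      # removed records get plain Bernoulli labels at the target prevalence
      rbinom(nrow(cohort), 1L, prevalence)
    )
  })
  list(cohort = cohort, catalog = catalog, effects = effects, config = config)
}
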