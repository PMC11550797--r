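#' Write a cohort to long-format CSV files
#'
#' Writes `cases.csv` (case_id, patient_id, visit_index, age, sex, outcome),
#' `exposures.csv` (one row per case-drug pair), optionally `catalog.csv`
#' and the ground-truth `effects.json`.
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory (created if needed).
#' @param catalog Optional drug catalog tibble.
#' @param effects Optional [true_effects()] object.
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, catalog = NULL, effects = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cases <- dplyr::select(
    cohort, "case_id", "patient_id", "visit_index", "age", "sex", "outcome"
  )
  readr::write_csv(cases, file.path(dir, "cases.csv"))
  exposures <- tibble::tibble(
    case_id = rep(cohort$case_id, lengths(cohort$drugs)),
    drug_name = unlist(cohort$drugs)
  )
  readr::write_csv(exposures, file.path(dir, "exposures.csv"))
  if (!is.null(catalog)) {
    readr::write_csv(catalog, file.path(dir, "catalog.csv"))
  }
  if (!is.null(effects)) {
    jsonlite::write_json(
      list(
        intercept = effects$intercept,
        drug_effects = as.list(effects$drug_effects),
        covariate_effects = as.list(effects$covariate_effects)
      ),
      file.path(dir, "effects.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' Read a cohort from long-format CSV files
#'
#' Counterpart of [write_cohort_csv()]. Cases absent from `exposures.csv`
#' get an empty medication list.
#'
#' @param dir Directory holding `cases.csv` and `exposures.csv` (and
#'   optionally `catalog.csv`).
#' @return A list with `cohort` and (possibly `NULL`) `catalog`.
#' @export
read_cohort_csv <- function(dir) {
  cases <- readr::read_csv(
    file.path(dir, "cases.csv"),
    col_types = readr::cols(
      case_id = "c", patient_id = "c", visit_index = "i",
      age = "d", sex = "c", outcome = "i"
    )
  )
  exposures <- readr::read_csv(
    file.path(dir, "exposures.csv"),
    col_types = readr::cols(case_id = "c", drug_name = "c")
  )
  split_drugs <- split(exposures$drug_name, exposures$case_id)
  cases$drugs <- lapply(cases$case_id, function(id) {
    split_drugs[[id]] %||% character(0)
  })
  cohort <- dplyr::select(
    cases, "case_id", "patient_id", "visit_index",
    "age", "sex", "drugs", "outcome"
  )
  catalog_path <- file.path(dir, "catalog.csv")
  catalog <- if (file.exists(catalog_path)) {
    readr::read_csv(catalog_path, col_types = readr::cols(
      drug_name = "c", .default = "l"
    ))
  } else {
    NULL
  }
  list(cohort = cohort, catalog = catalog)
}

#' Write a design matrix as CSV
#'
#' @param design Design tibble from [assemble_design_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  readr::write_csv(design, path)
  invisible(path)
}

#' Read a design matrix CSV
#'
#' @param path CSV path written by [write_design_csv()].
#' @return A tibble.
#' @export
read_design_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    case_id = "c", .default = "d"
  ), progress = FALSE)
}

# Long-format posterior draws table: chain, draw, one column per parameter.
draws_table <- function(fit) {
  d <- fit$draws
  n_draws <- dim(d)[1]
  n_chains <- dim(d)[2]
  out <- purrr::map_dfr(seq_len(n_chains), function(ch) {
    m <- matrix(d[, ch, ], nrow = n_draws)
    colnames(m) <- dimnames(d)[[3]]
    m <- tibble::as_tibble(m)
    dplyr::bind_cols(
      tibble::tibble(chain = ch, draw = seq_len(n_draws)), m
    )
  })
  if (inherits(fit$prior, "horseshoe_prior")) {
    out$tau <- as.vector(fit$shrinkage$tau)
    out$c2 <- as.vector(fit$shrinkage$c2)
  }
  out
}

#' Write posterior draws and diagnostics
#'
#' Writes a columnar draws CSV (chain, draw, one column per parameter, plus
#' `tau` and `c2` for horseshoe fits) and a diagnostics JSON (per-parameter
#' R-hat and effective sample size, thresholds, convergence flag).
#'
#' @param fit An `adr_fit`.
#' @param draws_path,diagnostics_path Output paths.
#' @return `draws_path`, invisibly.
#' @export
write_fit_outputs <- function(fit, draws_path, diagnostics_path) {
  readr::write_csv(draws_table(fit), draws_path)
  jsonlite::write_json(
    list(
      prior = class(fit$prior)[1],
      n = fit$n, p = fit$p,
      n_chains = fit$config$n_chains,
      n_draws = fit$config$n_draws,
      rhat_max = fit$config$rhat_max,
      ess_min = fit$config$ess_min,
      converged = fit$converged,
      parameters = fit$diagnostics
    ),
    diagnostics_path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(draws_path)
}
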