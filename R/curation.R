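#' Configure the curation pipeline
#'
#' Holds every rule the curation pipeline applies: the frequency threshold
#' and cap for drug selection, the combination products kept as their main
#' substance, the unspecific and supplement names removed from medication
#' lists, the CYP450 membership table, and the sex coding.
#'
#' @param min_count Minimum number of cases a substance must appear in to be
#'   eligible for selection (default 32), or `"auto"` to pick the threshold
#'   maximizing cumulative-exposure coverage minus retained-drug fraction
#'   (a knee criterion on the frequency curve).
#' @param top_n Maximum number of substances selected (default 100).
#' @param keep_main_substance Named character vector mapping a combination
#'   name to the single main substance kept instead of splitting. Defaults
#'   keep amoxicillin from amoxicillin/clavulanic acid, oxycodone from
#'   oxycodone/naloxone and tilidine from tilidine/naloxone.
#' @param unspecific_names Character vector of names too unspecific to keep
#'   (e.g. a drug documented only by class).
#' @param supplement_names Character vector of supplement / low-relevance
#'   names removed from medication lists.
#' @param cyp_table Data frame with column `drug_name` and the eight logical
#'   flags `cyp3a4_substrate`, ..., `cyp2c9_inhibitor`; drugs absent from the
#'   table count as all-false.
#'
#' @return An object of class `curation_config`.
#' @examples
#' cfg <- curation_config(min_count = 32, top_n = 100)
#' @export
curation_config <- function(min_count = 32,
                            top_n = 100,
                            keep_main_substance = c(
                              "amoxicillin/clavulanic acid" = "amoxicillin",
                              "oxycodone/naloxone" = "oxycodone",
                              "tilidine/naloxone" = "tilidine"
                            ),
                            unspecific_names = character(),
                            supplement_names = character(),
                            cyp_table = NULL) {
  if (!(identical(min_count, "auto") ||
    (is.numeric(min_count) && min_count >= 1))) {
    abort("`min_count` must be a number >= 1 or \"auto\".")
  }
  if (top_n < 1) abort("`top_n` must be at least 1.")
  if (any(grepl("/", keep_main_substance))) {
    abort("`keep_main_substance` values must be single substances (no \"/\").")
  }
  if (!is.null(cyp_table)) {
    missing_cols <- setdiff(
      c("drug_name", cyp_flag_names()), names(cyp_table)
    )
    if (length(missing_cols) > 0) {
      abort(paste0(
        "`cyp_table` lacks column(s): ", paste(missing_cols, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      min_count = min_count,
      top_n = as.integer(top_n),
      keep_main_substance = keep_main_substance,
      unspecific_names = unspecific_names,
      supplement_names = supplement_names,
      cyp_table = cyp_table
    ),
    class = "curation_config"
  )
}

#' Derive a curation configuration from a synthetic catalog
#'
#' Wires a [curation_config()] to a catalog from [build_drug_catalog()]:
#' entries flagged unspecific or supplement become the respective exclusion
#' lists, and the catalog's CYP flags become the CYP table.
#'
#' @param catalog A drug catalog tibble.
#' @param ... Passed on to [curation_config()].
#' @return A `curation_config`.
#' @export
config_from_catalog <- function(catalog, ...) {
  curation_config(
    unspecific_names = catalog$drug_name[catalog$is_unspecific],
    supplement_names = catalog$drug_name[catalog$is_supplement],
    cyp_table = catalog[, c("drug_name", cyp_flag_names())],
    ...
  )
}

#' Keep only each patient's first visit
#'
#' Subsequent visits may be affected by treatment received at the first
#' presentation, so only the record with the minimal `visit_index` per
#' patient is analyzed.
#'
#' @param cohort A cohort tibble with `patient_id` and `visit_index`.
#' @return The filtered cohort; the number of removed records is attached as
#'   attribute `"n_removed"`.
#' @export
keep_first_visits <- function(cohort) {
  if (anyDuplicated(cohort[, c("patient_id", "visit_index")]) > 0) {
    abort("Duplicate (patient_id, visit_index) pairs in cohort.")
  }
  out <- cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(.data$visit_index == min(.data$visit_index)) |>
    dplyr::ungroup()
  attr(out, "n_removed") <- nrow(cohort) - nrow(out)
  out
}

#' Drop cases with missing medication records
#'
#' @param cohort A cohort tibble with a `drugs` list column.
#' @return The filtered cohort; removed-record count attached as attribute
#'   `"n_removed"`.
#' @export
drop_missing_medication <- function(cohort) {
  keep <- lengths(cohort$drugs) > 0
  out <- cohort[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Normalize one medication list
#'
#' Applies the medication-name rules: names in the keep-main map are replaced
#' by their main substance; other `"/"`-joined combination names are split
#' into components; unspecific and supplement names are removed and counted;
#' duplicates are collapsed.
#'
#' @param drugs Character vector of documented drug names for one case.
#' @param config A [curation_config()].
#' @return A list with `drugs` (normalized character vector) and `n_dropped`
#'   (count of removed unspecific/supplement names).
#' @examples
#' normalize_drugs(c("oxycodone/naloxone", "a/b"), curation_config())
#' @export
normalize_drugs <- function(drugs, config = curation_config()) {
  out <- character(0)
  n_dropped <- 0L
  for (nm in unique(drugs)) {
    comps <- if (nm %in% names(config$keep_main_substance)) {
      config$keep_main_substance[[nm]]
    } else if (grepl("/", nm, fixed = TRUE)) {
      strsplit(nm, "/", fixed = TRUE)[[1]]
    } else {
      nm
    }
    drop <- comps %in% config$unspecific_names |
      comps %in% config$supplement_names
    n_dropped <- n_dropped + sum(drop)
    out <- c(out, comps[!drop])
  }
  list(drugs = unique(out), n_dropped = n_dropped)
}

# Vectorized normalization over a cohort; memoizes per unique raw name.
normalize_cohort <- function(cohort, config = curation_config()) {
  if (all(c("drugs_normalized", "n_dropped_norm") %in% names(cohort))) {
    return(cohort) # already normalized; idempotent
  }
  uniq <- unique(unlist(cohort$drugs))
  lookup <- lapply(uniq, function(nm) normalize_drugs(nm, config))
  names(lookup) <- uniq
  res <- lapply(cohort$drugs, function(d) {
    if (length(d) == 0) {
      return(list(drugs = character(0), n_dropped = 0L))
    }
    parts <- lookup[unique(d)]
    list(
      drugs = unique(unlist(lapply(parts, `[[`, "drugs"))),
      n_dropped = sum(vapply(parts, `[[`, integer(1), "n_dropped"))
    )
  })
  cohort$drugs_normalized <- lapply(res, `[[`, "drugs")
  cohort$n_dropped_norm <- vapply(res, `[[`, integer(1), "n_dropped")
  cohort
}

#' Select the analysis drugs by frequency
#'
#' Counts, for each normalized substance, the number of cases exposed to it,
#' applies the frequency threshold (fixed `min_count`, or the `"auto"` knee
#' criterion maximizing cumulative-exposure coverage fraction minus
#' retained-drug fraction), and keeps at most `top_n` substances, most
#' frequent first with alphabetical tie-break.
#'
#' @param cohort A cohort tibble (normalized internally if needed).
#' @param config A [curation_config()].
#' @return A list with `selected` (character vector, by descending
#'   frequency), `threshold` (the frequency threshold used), and
#'   `diagnostics` (tibble of candidate thresholds with coverage and
#'   retained-drug fractions).
#' @export
select_top_drugs <- function(cohort, config = curation_config()) {
  cohort <- normalize_cohort(cohort, config)
  freq_tab <- table(unlist(lapply(cohort$drugs_normalized, unique)))
  freq <- tibble::tibble(
    drug = names(freq_tab),
    n = as.integer(freq_tab)
  )
  total <- sum(freq$n)
  cand <- sort(unique(freq$n))
  diagnostics <- tibble::tibble(
    threshold = cand,
    coverage = vapply(
      cand, function(t) sum(freq$n[freq$n >= t]) / total, numeric(1)
    ),
    retained_fraction = vapply(
      cand, function(t) mean(freq$n >= t), numeric(1)
    )
  )
  diagnostics$objective <- diagnostics$coverage - diagnostics$retained_fraction

  threshold <- if (identical(config$min_count, "auto")) {
    diagnostics$threshold[which.max(diagnostics$objective)]
  } else {
    config$min_count
  }
  eligible <- freq[freq$n >= threshold, ]
  if (nrow(eligible) < 1) {
    abort("No drug survives the frequency threshold.")
  }
  eligible <- eligible[order(-eligible$n, eligible$drug), ]
  selected <- head(eligible$drug, config$top_n)
  list(selected = selected, threshold = threshold, diagnostics = diagnostics)
}

#' Count a case's excluded drugs
#'
#' Number of a case's normalized drugs that are not in the selected analysis
#' list, plus any unspecific/supplement names already dropped during
#' normalization.
#'
#' @param drugs Normalized drug names of one case.
#' @param selected Character vector of selected analysis drugs.
#' @param n_dropped Count of names dropped during normalization (default 0).
#' @return Integer count.
#' @examples
#' count_excluded(c("a", "b", "c"), selected = c("a", "b"))
#' @export
count_excluded <- function(drugs, selected, n_dropped = 0L) {
  as.integer(sum(!drugs %in% selected) + n_dropped)
}

#' Count CYP450 substrates and inhibitors in a medication list
#'
#' @param drugs Normalized drug names of one case.
#' @param cyp_table CYP membership table (see [curation_config()]); drugs
#'   absent from the table contribute 0 to all counts. `NULL` means no drug
#'   has any CYP membership.
#' @return Named integer vector of the eight counts (`cyp3a4_substrates`,
#'   ..., `cyp2c9_inhibitors`).
#' @examples
#' tab <- data.frame(
#'   drug_name = "x", cyp3a4_substrate = TRUE, cyp2d6_substrate = FALSE,
#'   cyp2c19_substrate = FALSE, cyp2c9_substrate = FALSE,
#'   cyp3a4_inhibitor = FALSE, cyp2d6_inhibitor = FALSE,
#'   cyp2c19_inhibitor = FALSE, cyp2c9_inhibitor = FALSE
#' )
#' annotate_cyp(c("x", "y"), tab)
#' @export
annotate_cyp <- function(drugs, cyp_table = NULL) {
  counts <- setNames(
    integer(length(cyp_flag_names())), paste0(cyp_flag_names(), "s")
  )
  if (is.null(cyp_table) || length(drugs) == 0) {
    return(counts)
  }
  rows <- cyp_table[cyp_table$drug_name %in% drugs, , drop = FALSE]
  for (flag in cyp_flag_names()) {
    counts[[paste0(flag, "s")]] <- as.integer(sum(rows[[flag]]))
  }
  counts
}

# Per-cohort CYP counts as a tibble (one row per case).
annotate_cyp_cohort <- function(cohort, cyp_table = NULL) {
  cohort <- normalize_cohort(cohort)
  mat <- t(vapply(
    cohort$drugs_normalized,
    function(d) annotate_cyp(d, cyp_table),
    setNames(integer(8), paste0(cyp_flag_names(), "s"))
  ))
  tibble::as_tibble(mat)
}

#' Assemble the analysis design matrix
#'
#' Builds the case-by-predictor analysis table: one binary indicator column
#' per selected drug, the eleven clinical covariates (age, female sex,
#' number of excluded drugs, and the eight CYP450 substrate/inhibitor
#' counts), and the binary outcome, with rows in ascending `case_id` order.
#'
#' The conventional "rows x columns" size of such a table counts the drug
#' indicators, covariates and outcome but not the case identifier: with 100
#' selected drugs the design is n x 112 (100 drugs + 11 covariates +
#' 1 outcome), while the returned tibble additionally carries `case_id`.
#'
#' @param cohort A curated cohort tibble (first visits, no missing
#'   medication, outcomes assigned).
#' @param selected Character vector of selected drugs (see
#'   [select_top_drugs()]).
#' @param config A [curation_config()].
#' @return A list with `design` (tibble) and `report` (a curation report
#'   list; counts filled in by [curate_cohort()] when called from the
#'   pipeline).
#' @export
assemble_design_matrix <- function(cohort, selected,
                                   config = curation_config()) {
  if (length(selected) == 0) abort("`selected` must be non-empty.")
  if (anyNA(cohort$outcome)) {
    abort("Every case must have a non-missing outcome.")
  }
  cohort <- normalize_cohort(cohort, config)
  cohort <- dplyr::arrange(cohort, .data$case_id)

  drug_block <- vapply(
    selected,
    function(d) {
      as.integer(vapply(
        cohort$drugs_normalized, function(x) d %in% x, logical(1)
      ))
    },
    integer(nrow(cohort))
  )
  colnames(drug_block) <- selected

  n_excluded <- mapply(
    count_excluded,
    cohort$drugs_normalized,
    n_dropped = cohort$n_dropped_norm,
    MoreArgs = list(selected = selected)
  )
  cyp <- annotate_cyp_cohort(cohort, config$cyp_table)

  design <- dplyr::bind_cols(
    tibble::tibble(case_id = cohort$case_id),
    tibble::as_tibble(drug_block),
    tibble::tibble(
      age = as.numeric(cohort$age),
      sex_female = as.integer(cohort$sex == "female"),
      n_excluded = as.integer(n_excluded)
    ),
    cyp,
    tibble::tibble(outcome = as.integer(cohort$outcome))
  )
  report <- list(
    n_final = nrow(design),
    selected_drugs = selected,
    column_names = setdiff(names(design), "case_id")
  )
  list(design = design, report = report)
}

#' Run the full curation pipeline
#'
#' Applies the curation stages in order: first-visit filter, missing-
#' medication exclusion, medication normalization, frequency-based drug
#' selection, covariate construction, design-matrix assembly.
#'
#' @param cohort A raw cohort tibble with outcomes assigned.
#' @param config A [curation_config()].
#' @return A list with `design` (the analysis tibble), `report` (curation
#'   report: record counts per stage, substance counts, selected drugs,
#'   threshold, per-stage timestamps), and `selection` (the
#'   [select_top_drugs()] result).
#' @examples
#' spec <- cohort_spec(n_cases = 120, catalog_size = 40, seed = 5)
#' catalog <- build_drug_catalog(spec)
#' cohort <- sample_cohort(spec, catalog) |>
#'   assign_outcomes(true_effects(intercept = -1), seed = 6)
#' res <- curate_cohort(cohort, config_from_catalog(catalog,
#'   min_count = 2, top_n = 10
#' ))
#' dim(res$design)
#' @export
curate_cohort <- function(cohort, config = curation_config()) {
  times <- list(start = Sys.time())
  n_raw <- nrow(cohort)

  first <- keep_first_visits(cohort)
  n_removed_repeat <- attr(first, "n_removed")
  times$first_visits <- Sys.time()

  kept <- drop_missing_medication(first)
  n_removed_missing <- attr(kept, "n_removed")
  times$missing_medication <- Sys.time()

  kept <- normalize_cohort(kept, config)
  n_substances_raw <- length(unique(unlist(kept$drugs_normalized)))
  times$normalize <- Sys.time()

  selection <- select_top_drugs(kept, config)
  freq_tab <- table(unlist(lapply(kept$drugs_normalized, unique)))
  n_after_threshold <- sum(freq_tab >= selection$threshold)
  times$select <- Sys.time()

  asm <- assemble_design_matrix(kept, selection$selected, config)
  times$assemble <- Sys.time()

  report <- list(
    n_raw = n_raw,
    n_removed_repeat = n_removed_repeat,
    n_removed_missing_med = n_removed_missing,
    n_final = nrow(asm$design),
    n_substances_raw = n_substances_raw,
    n_substances_after_threshold = as.integer(n_after_threshold),
    threshold = selection$threshold,
    selected_drugs = selection$selected,
    column_names = asm$report$column_names,
    stage_times = lapply(times, format, usetz = TRUE)
  )
  stopifnot(
    report$n_final ==
      report$n_raw - report$n_removed_repeat - report$n_removed_missing_med
  )
  list(design = asm$design, report = report, selection = selection)
}
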