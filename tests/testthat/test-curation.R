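test_that("first-visit filter keeps the minimal visit per patient", {
  cohort <- make_cohort(
    list("a", "b", "c"),
    patient_id = c("P1", "P1", "P2"),
    visit_index = c(1L, 2L, 1L)
  )
  out <- keep_first_visits(cohort)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_removed"), 1)
  expect_setequal(out$patient_id, c("P1", "P2"))
  expect_true(all(out$visit_index == 1))

  # identity on a cohort without repeats
  no_rep <- make_cohort(list("a", "b"))
  out2 <- keep_first_visits(no_rep)
  expect_equal(attr(out2, "n_removed"), 0)
  expect_equal(out2, no_rep, ignore_attr = TRUE)

  dup <- make_cohort(
    list("a", "b"),
    patient_id = c("P1", "P1"), visit_index = c(1L, 1L)
  )
  expect_error(keep_first_visits(dup), "Duplicate")
})

test_that("missing-medication exclusion removes empty lists only", {
  cohort <- make_cohort(list("a", character(0), c("b", "c")))
  out <- drop_missing_medication(cohort)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_removed"), 1)

  full <- make_cohort(list("a", "b"))
  out2 <- drop_missing_medication(full)
  expect_equal(attr(out2, "n_removed"), 0)
  expect_equal(nrow(out2), 2)
})

test_that("medication normalization applies keep-main, split and drop rules", {
  cfg <- curation_config(
    unspecific_names = c("NSAID"),
    supplement_names = c("calcium carbonate")
  )
  expect_equal(
    normalize_drugs("oxycodone/naloxone", cfg),
    list(drugs = "oxycodone", n_dropped = 0L)
  )
  expect_equal(
    normalize_drugs("NSAID", cfg),
    list(drugs = character(0), n_dropped = 1L)
  )
  expect_equal(
    normalize_drugs("a/b", cfg),
    list(drugs = c("a", "b"), n_dropped = 0L)
  )
  # supplements dropped, duplicates collapsed across entries
  out <- normalize_drugs(
    c("a/b", "b", "calcium carbonate", "amoxicillin/clavulanic acid"), cfg
  )
  expect_setequal(out$drugs, c("a", "b", "amoxicillin"))
  expect_equal(out$n_dropped, 1L)
  # normalizing an already-normalized list changes nothing
  again <- normalize_drugs(out$drugs, cfg)
  expect_setequal(again$drugs, out$drugs)
  expect_equal(again$n_dropped, 0L)
})

test_that("frequency-based selection applies threshold, cap and tie-break", {
  # frequencies A:50 B:40 C:31 D:10
  lists <- lapply(seq_len(50), function(i) {
    c("A", if (i <= 40) "B", if (i <= 31) "C", if (i <= 10) "D")
  })
  cohort <- make_cohort(lists)
  sel <- select_top_drugs(cohort, curation_config(min_count = 32))
  expect_equal(sel$selected, c("A", "B"))
  expect_equal(sel$threshold, 32)

  # auto knee criterion: coverage minus retained fraction, enumerated by hand
  freq <- c(A = 50, B = 40, C = 31, D = 10)
  cand <- sort(unique(freq))
  obj <- vapply(cand, function(t) {
    sum(freq[freq >= t]) / sum(freq) - mean(freq >= t)
  }, numeric(1))
  best <- cand[which.max(obj)]
  sel_auto <- select_top_drugs(cohort, curation_config(min_count = "auto"))
  expect_equal(sel_auto$threshold, best)
  expect_equal(sel_auto$selected, names(freq)[freq >= best])

  # 150 eligible drugs capped at the 100 most frequent
  # drug j appears in cases 1..(200 - j): frequencies 199 down to 50
  drugs150 <- sprintf("d%03d", 1:150)
  lists2 <- lapply(seq_len(200), function(i) {
    drugs150[200 - seq_len(150) >= i]
  })
  lists2 <- lists2[lengths(lists2) > 0]
  cohort2 <- make_cohort(lists2)
  sel2 <- select_top_drugs(cohort2, curation_config(min_count = 32, top_n = 100))
  expect_length(sel2$selected, 100)
  expect_setequal(sel2$selected, drugs150[1:100])

  # alphabetical tie-break at equal frequency
  cohort3 <- make_cohort(lapply(1:40, function(i) c("B", "A")))
  sel3 <- select_top_drugs(
    cohort3, curation_config(min_count = 1, top_n = 1)
  )
  expect_equal(sel3$selected, "A")

  expect_error(
    select_top_drugs(cohort3, curation_config(min_count = 99)),
    "No drug survives"
  )
})

test_that("excluded-drug counting includes normalization drops", {
  expect_equal(
    count_excluded(sprintf("d%d", 1:9), selected = sprintf("d%d", 1:7)), 2L
  )
  expect_equal(count_excluded(c("a", "b"), selected = c("a", "b")), 0L)
  expect_equal(
    count_excluded(c("a", "b"), selected = "a", n_dropped = 3L), 4L
  )
})

test_that("CYP annotation counts substrates and inhibitors independently", {
  tab <- make_cyp_table(
    c("drugX", "drugY", "drugZ"),
    drugX = "cyp3a4_substrate",
    drugY = "cyp3a4_inhibitor",
    drugZ = c("cyp2c19_substrate", "cyp2c19_inhibitor")
  )
  counts <- annotate_cyp(c("drugX", "drugY"), tab)
  expect_equal(counts[["cyp3a4_substrates"]], 1L)
  expect_equal(counts[["cyp3a4_inhibitors"]], 1L)
  expect_equal(sum(counts), 2L)

  expect_equal(sum(annotate_cyp(character(0), tab)), 0L)

  # a drug that is both substrate and inhibitor contributes to both counts
  both <- annotate_cyp("drugZ", tab)
  expect_equal(both[["cyp2c19_substrates"]], 1L)
  expect_equal(both[["cyp2c19_inhibitors"]], 1L)

  # drugs absent from the table count as all-false
  expect_equal(sum(annotate_cyp("unknown", tab)), 0L)
})

test_that("design assembly produces indicators, covariates and outcome", {
  cohort <- make_cohort(
    list(c("a"), c("a", "b", "x")),
    sex = c("male", "male"), outcome = c(0L, 1L)
  )
  res <- assemble_design_matrix(cohort, selected = c("a", "b"))
  expect_equal(unname(unlist(res$design[1, c("a", "b")])), c(1L, 0L))
  expect_equal(unname(unlist(res$design[2, c("a", "b")])), c(1L, 1L))
  expect_equal(res$design$n_excluded, c(0L, 1L))
  expect_true(all(res$design$sex_female == 0))
  # column accounting: selected + 11 covariates + outcome (case_id extra)
  expect_equal(ncol(res$design) - 1, 2 + 11 + 1)

  expect_error(assemble_design_matrix(cohort, character(0)), "non-empty")
  cohort_na <- make_cohort(list("a"))
  cohort_na$outcome <- NA_integer_
  expect_error(assemble_design_matrix(cohort_na, "a"), "outcome")
})

test_that("curation conserves records and reconstructs frequencies", {
  for (seed in c(21, 22, 23)) {
    spec <- cohort_spec(
      n_cases = 300, n_repeat_visits = 20, n_missing_medication = 4,
      catalog_size = 60, seed = seed
    )
    catalog <- build_drug_catalog(spec)
    cohort <- sample_cohort(spec, catalog)
    cohort <- assign_outcomes(
      cohort, true_effects(intercept = -1.5),
      seed = seed
    )
    cfg <- config_from_catalog(catalog, min_count = 3, top_n = 25)
    res <- curate_cohort(cohort, cfg)
    r <- res$report

    # conservation
    expect_equal(
      r$n_final + r$n_removed_repeat + r$n_removed_missing_med, r$n_raw
    )

    # per case: selected-drug indicators + n_excluded = normalized list size
    surv <- adrsignal:::normalize_cohort(
      drop_missing_medication(keep_first_visits(cohort)), cfg
    )
    surv <- dplyr::arrange(surv, case_id)
    drug_cols <- as.matrix(res$design[res$selection$selected])
    expect_equal(
      unname(rowSums(drug_cols) + res$design$n_excluded -
        surv$n_dropped_norm),
      unname(lengths(surv$drugs_normalized))
    )

    # indicator column sums equal case frequencies among survivors
    freq <- table(unlist(lapply(surv$drugs_normalized, unique)))
    expect_equal(
      unname(colSums(drug_cols)),
      unname(as.integer(freq[res$selection$selected]))
    )
  }
})

test_that("curation is idempotent on an already-curated cohort", {
  spec <- cohort_spec(
    n_cases = 200, n_repeat_visits = 10, n_missing_medication = 2,
    catalog_size = 40, seed = 9
  )
  catalog <- build_drug_catalog(spec)
  cohort <- sample_cohort(spec, catalog)
  cohort <- assign_outcomes(cohort, true_effects(intercept = -1), seed = 90)
  cfg <- config_from_catalog(catalog, min_count = 2, top_n = 15)

  once <- curate_cohort(cohort, cfg)
  filtered <- drop_missing_medication(keep_first_visits(cohort))
  twice <- curate_cohort(filtered, cfg)
  expect_equal(twice$design, once$design)
  expect_equal(twice$report$n_removed_repeat, 0)
  expect_equal(twice$report$n_removed_missing_med, 0)
})
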