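#' Run the end-to-end signal-detection pipeline
#'
#' Orchestrates simulate (or ingest) -> curate -> fit (horseshoe and/or
#' lasso) -> classify -> report from a single YAML (or list) configuration,
#' writing every stage artifact plus a machine-readable run manifest to the
#' output directory.
#'
#' The configuration has sections:
#' \describe{
#'   \item{seed}{integer; master seed for every stage (required).}
#'   \item{out_dir}{output directory (required).}
#'   \item{simulate}{either `fixture: true` with `outcome: fall|bleeding`,
#'     or a `spec:` block of [cohort_spec()] fields with optional
#'     `effects:` (`intercept`, `drug_effects`, `covariate_effects`).
#'     Mutually exclusive with `ingest`.}
#'   \item{ingest}{`dir:` with cohort CSVs (see [read_cohort_csv()]) and the
#'     `outcome:` column name.}
#'   \item{curation}{[curation_config()] fields (`min_count`, `top_n`).}
#'   \item{fit}{`priors:` (subset of `horseshoe`, `lasso`), `p0`,
#'     `laplace_scale`, `n_chains`, `n_warmup`, `n_draws`.}
#'   \item{classify}{`level_light` (default 0.5) and `level_strong`
#'     (default 0.9).}
#'   \item{report}{`forest_plots: true|false`.}
#' }
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list.
#' @return The run manifest (named list), invisibly: configuration snapshot,
#'   seeds, content hashes of every stage output, package/R versions, the
#'   curation report, and per-prior diagnostics summaries. Written to
#'   `manifest.json` in `out_dir`. The manifest element `status` is 0 for a
#'   clean run and 2 when convergence diagnostics were flagged.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_pipeline_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  warnings_seen <- character(0)
  files <- character(0)

  log_stage <- function(stage, event, ...) {
    kv <- list(...)
    extra <- if (length(kv) > 0) {
      paste0(" ", paste0(names(kv), "=", unlist(kv), collapse = " "))
    } else {
      ""
    }
    inform(sprintf("[%s] %s%s", stage, event, extra))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  # --- simulate / ingest -----------------------------------------------
  sim <- run_stage("simulate", {
    if (!is.null(cfg$ingest)) {
      log_stage("ingest", "reading", dir = cfg$ingest$dir)
      ing <- read_cohort_csv(cfg$ingest$dir)
      oc <- cfg$ingest$outcome
      if (!oc %in% names(ing$cohort)) {
        abort(paste0("Outcome column `", oc, "` not found in ingested cases."))
      }
      ing$cohort$outcome <- ing$cohort[[oc]]
      if (!is.null(ing$catalog)) {
        ing$config <- config_from_catalog(ing$catalog)
      }
      ing
    } else if (isTRUE(cfg$simulate$fixture)) {
      outcome <- cfg$simulate$outcome %||% "fall"
      log_stage("simulate", "fixture", outcome = outcome)
      fixture_cohort(seed = seed, outcome = outcome)
    } else {
      spec <- do.call(cohort_spec, c(cfg$simulate$spec, list(seed = seed)))
      catalog <- build_drug_catalog(spec)
      eff_cfg <- cfg$simulate$effects %||% list()
      effects <- true_effects(
        intercept = eff_cfg$intercept %||% qlogis(0.06),
        drug_effects = unlist(eff_cfg$drug_effects) %||% numeric(),
        covariate_effects = unlist(eff_cfg$covariate_effects) %||% numeric()
      )
      config_cur <- config_from_catalog(catalog)
      cohort <- sample_cohort(spec, catalog)
      cohort <- assign_outcomes(
        cohort, effects, config_cur,
        seed = derive_seed(seed, 71L)
      )
      list(
        cohort = cohort, catalog = catalog,
        effects = effects, config = config_cur
      )
    }
  })
  log_stage("simulate", "done", n_cases = nrow(sim$cohort))
  write_cohort_csv(sim$cohort, out_dir, sim$catalog, sim$effects)
  files <- c(
    files,
    file.path(out_dir, c("cases.csv", "exposures.csv")),
    if (!is.null(sim$catalog)) file.path(out_dir, "catalog.csv"),
    if (!is.null(sim$effects)) file.path(out_dir, "effects.json")
  )

  # --- curate ----------------------------------------------------------
  cur_cfg_args <- cfg$curation %||% list()
  base_config <- sim$config %||% curation_config()
  cur_config <- curation_config(
    min_count = cur_cfg_args$min_count %||% base_config$min_count,
    top_n = cur_cfg_args$top_n %||% base_config$top_n,
    keep_main_substance = base_config$keep_main_substance,
    unspecific_names = base_config$unspecific_names,
    supplement_names = base_config$supplement_names,
    cyp_table = base_config$cyp_table
  )
  cur <- run_stage("curate", curate_cohort(sim$cohort, cur_config))
  log_stage("curate", "done",
    n_final = cur$report$n_final,
    n_selected = length(cur$report$selected_drugs)
  )
  write_design_csv(cur$design, file.path(out_dir, "design.csv"))
  report_json <- cur$report
  jsonlite::write_json(
    report_json, file.path(out_dir, "curation_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  files <- c(files, file.path(out_dir, "design.csv"))

  # --- fit / classify / report ----------------------------------------
  fit_cfg <- cfg$fit
  priors <- fit_cfg$priors %||% c("horseshoe", "lasso")
  level_light <- cfg$classify$level_light %||% 0.5
  level_strong <- cfg$classify$level_strong %||% 0.9
  diagnostics_summary <- list()

  for (pr in priors) {
    prior <- if (pr == "horseshoe") {
      horseshoe_prior(p0 = fit_cfg$p0 %||% 5)
    } else {
      laplace_prior(scale = fit_cfg$laplace_scale %||% 1)
    }
    fconf <- fit_config(
      n_chains = fit_cfg$n_chains %||% 4L,
      n_warmup = fit_cfg$n_warmup %||% 1000L,
      n_draws = fit_cfg$n_draws %||% 1000L,
      seed = derive_seed(seed, match(pr, c("horseshoe", "lasso")))
    )
    log_stage("fit", "start",
      prior = pr, n = nrow(cur$design),
      p = length(cur$report$column_names) - 1
    )
    fit <- run_stage(
      "fit",
      withCallingHandlers(
        fit_shrinkage(cur$design, prior, config = fconf),
        warning = function(w) {
          warnings_seen <<- c(warnings_seen, conditionMessage(w))
          invokeRestart("muffleWarning")
        },
        message = function(m) invisible(invokeRestart("muffleMessage"))
      )
    )
    draws_path <- file.path(out_dir, paste0("draws_", pr, ".csv"))
    diag_path <- file.path(out_dir, paste0("diagnostics_", pr, ".json"))
    write_fit_outputs(fit, draws_path, diag_path)
    log_stage("fit", "done",
      prior = pr,
      max_rhat = signif(max(fit$diagnostics$rhat), 4),
      converged = fit$converged
    )

    summaries <- run_stage(
      "classify",
      tidy_at_levels(fit, level_light, level_strong)
    )
    table <- build_signal_table(summaries)
    sig_csv <- file.path(out_dir, paste0("signals_", pr, ".csv"))
    readr::write_csv(table, sig_csv)
    jsonlite::write_json(
      table, file.path(out_dir, paste0("signals_", pr, ".json")),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    log_stage("classify", "done", prior = pr, n_signals = nrow(table))

    plot_files <- character(0)
    if (isTRUE(cfg$report$forest_plots %||% TRUE)) {
      full_tab <- build_signal_table(summaries, keep_all = TRUE)
      plot <- plot_forest(
        full_tab,
        outcome_label = paste0(pr, " prior")
      )
      plot_path <- file.path(out_dir, paste0("forest_", pr, ".svg"))
      run_stage("report", save_forest_plot(plot, plot_path))
      plot_files <- plot_path
      log_stage("report", "done", prior = pr)
    }
    files <- c(
      files, draws_path, diag_path, sig_csv,
      file.path(out_dir, paste0("signals_", pr, ".json")), plot_files
    )
    diagnostics_summary[[pr]] <- list(
      max_rhat = max(fit$diagnostics$rhat),
      min_ess = min(fit$diagnostics$ess),
      converged = fit$converged
    )
  }

  manifest <- list(
    package = "adrsignal",
    package_version = as.character(utils::packageVersion("adrsignal")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = cfg,
    files = setNames(
      lapply(files, hash_file),
      basename(files)
    ),
    curation_report = report_json[setdiff(names(report_json), "stage_times")],
    diagnostics = diagnostics_summary,
    warnings = warnings_seen,
    status = if (all(vapply(diagnostics_summary, `[[`, logical(1), "converged"))) 0L else 2L
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  log_stage("pipeline", "done", status = manifest$status)
  invisible(manifest)
}

# tidy() at configurable light/strong interval levels
tidy_at_levels <- function(fit, level_light = 0.5, level_strong = 0.9) {
  terms <- dimnames(fit$draws)[[3]]
  summ <- purrr::map_dfr(terms, function(tm) {
    d <- pooled_draws(fit, tm)
    ci50 <- credible_interval(d, level_light)
    ci90 <- credible_interval(d, level_strong)
    tibble::tibble(
      term = tm, estimate = median(d),
      ci50_lo = ci50[1], ci50_hi = ci50[2],
      ci90_lo = ci90[1], ci90_hi = ci90[2]
    )
  })
  summ$role <- dplyr::case_when(
    summ$term == "(Intercept)" ~ "intercept",
    summ$term %in% covariate_names() ~ "covariate",
    TRUE ~ "drug"
  )
  summ
}

hash_file <- function(path) {
  rlang::hash(readBin(path, "raw", file.size(path)))
}

validate_pipeline_config <- function(cfg) {
  required <- c("seed", "out_dir")
  missing <- required[!required %in% names(cfg)]
  if (length(missing) > 0) {
    abort(paste0(
      "Pipeline config is missing required key(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (is.null(cfg$simulate) && is.null(cfg$ingest)) {
    abort("Pipeline config needs a `simulate` or `ingest` section.")
  }
  if (!is.null(cfg$ingest)) {
    if (is.null(cfg$ingest$dir)) {
      abort("Pipeline config key `ingest.dir` is missing.")
    }
    if (is.null(cfg$ingest$outcome)) {
      abort("Pipeline config key `ingest.outcome` (outcome column name) is missing.")
    }
  }
  if (!is.null(cfg$fit$priors)) {
    bad <- setdiff(cfg$fit$priors, c("horseshoe", "lasso"))
    if (length(bad) > 0) {
      abort(paste0("Unknown prior(s) in `fit.priors`: ", paste(bad, collapse = ", ")))
    }
  }
  invisible(cfg)
}
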