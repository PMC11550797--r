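#' Build a synthetic drug catalog
#'
#' Generates the universe of substances a synthetic cohort can be exposed to:
#' mostly plain substances, plus configurable fractions of combination
#' products (two plain components joined as `"a/b"`), unspecific drug names
#' (e.g. a drug documented only as an analgesic), and food supplements.
#' Each entry carries eight CYP450 membership flags (substrate and inhibitor
#' of CYP3A4, CYP2D6, CYP2C19 and CYP2C9), assigned independently per
#' enzyme and role.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; defaults to a seed derived from
#'   `spec$seed`.
#'
#' @return A tibble with one row per catalog entry and columns `drug_name`,
#'   `is_combination`, `is_unspecific`, `is_supplement`, and the eight logical
#'   CYP flag columns (`cyp3a4_substrate`, ..., `cyp2c9_inhibitor`).
#' @examples
#' catalog <- build_drug_catalog(cohort_spec(catalog_size = 20, seed = 1))
#' nrow(catalog)
#' @export
build_drug_catalog <- function(spec, seed = NULL) {
  validate_cohort_spec(spec)
  seed <- seed %||% derive_seed(spec$seed, 11L)
  size <- spec$catalog_size
  local_seed(seed, {
    n_unspec <- round(size * spec$unspecific_fraction)
    n_supp <- round(size * spec$supplement_fraction)
    n_combo <- round(size * spec$combination_fraction)
    n_plain <- size - n_unspec - n_supp - n_combo
    if (n_plain < 2 && n_combo > 0) {
      # combination products need two plain components
      n_plain <- n_plain + n_combo
      n_combo <- 0L
    }
    width <- max(4L, nchar(as.character(size)))
    plain <- sprintf(paste0("drug%0", width, "d"), seq_len(n_plain))
    unspec <- if (n_unspec > 0) {
      sprintf("unspecific_class%03d", seq_len(n_unspec))
    } else {
      character(0)
    }
    supp <- if (n_supp > 0) {
      sprintf("supplement%03d", seq_len(n_supp))
    } else {
      character(0)
    }
    combos <- character(0)
    if (n_combo > 0) {
      seen <- character(0)
      while (length(combos) < n_combo) {
        comp <- sample(plain, 2L)
        nm <- paste(comp, collapse = "/")
        if (!nm %in% seen) {
          seen <- c(seen, nm)
          combos <- c(combos, nm)
        }
      }
    }
    name <- c(plain, combos, unspec, supp)
    type <- rep(
      c("plain", "combination", "unspecific", "supplement"),
      c(n_plain, length(combos), n_unspec, n_supp)
    )
    # popularity rank is a random interleaving of all entry types
    ord <- sample.int(length(name))
    cat <- tibble::tibble(
      drug_name = name[ord],
      is_combination = type[ord] == "combination",
      is_unspecific = type[ord] == "unspecific",
      is_supplement = type[ord] == "supplement"
    )
    for (enzyme in c("cyp3a4", "cyp2d6", "cyp2c19", "cyp2c9")) {
      cat[[paste0(enzyme, "_substrate")]] <-
        runif(size) < spec$cyp_substrate_prob
      cat[[paste0(enzyme, "_inhibitor")]] <-
        runif(size) < spec$cyp_inhibitor_prob
    }
    cat
  })
}

cyp_flag_names <- function() {
  as.vector(outer(
    c("cyp3a4", "cyp2d6", "cyp2c19", "cyp2c9"),
    c("substrate", "inhibitor"),
    paste,
    sep = "_"
  ))
}
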