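#' Equal-tailed credible interval
#'
#' Quantile-based interval at probabilities `(1 - level)/2` and
#' `1 - (1 - level)/2`, with linear interpolation between order statistics
#' (the convention is fixed so that displayed intervals are reproducible).
#'
#' @param draws Numeric vector of posterior draws (at least 2).
#' @param level Interval mass in (0, 1).
#' @return Length-2 numeric vector `(lo, hi)`.
#' @examples
#' credible_interval(1:100, 0.5) # (25.75, 75.25)
#' @export
credible_interval <- function(draws, level) {
  if (length(draws) < 2) abort("Need at least 2 draws.")
  if (!(level > 0 && level < 1)) abort("`level` must lie in (0, 1).")
  a <- (1 - level) / 2
  unname(quantile(draws, c(a, 1 - a), type = 7, names = FALSE))
}

#' Classify a predictor from its credible intervals
#'
#' A predictor whose 50% credible interval excludes zero is at least a light
#' signal; if the 90% interval also excludes zero it is a strong signal, in
#' the direction of the coefficient. Interval endpoints exactly at zero are
#' treated as covering zero (conservative). Vectorized over predictors.
#'
#' @param ci50_lo,ci50_hi,ci90_lo,ci90_hi Interval endpoints.
#' @return Character vector with values `"strong_positive"`,
#'   `"light_positive"`, `"none"`, `"light_negative"`, `"strong_negative"`.
#' @examples
#' classify_signal(0.54, 0.96, 0.18, 1.23) # strong_positive
#' classify_signal(0.06, 0.41, -0.02, 0.66) # light_positive
#' @export
classify_signal <- function(ci50_lo, ci50_hi, ci90_lo, ci90_hi) {
  light_pos <- ci50_lo > 0
  light_neg <- ci50_hi < 0
  strong_pos <- light_pos & ci90_lo > 0
  strong_neg <- light_neg & ci90_hi < 0
  dplyr::case_when(
    strong_pos ~ "strong_positive",
    light_pos ~ "light_positive",
    strong_neg ~ "strong_negative",
    light_neg ~ "light_negative",
    TRUE ~ "none"
  )
}

signal_class_levels <- function() {
  c(
    "strong_positive", "light_positive",
    "light_negative", "strong_negative", "none"
  )
}

#' Build a signal table from coefficient summaries
#'
#' Classifies every summarized coefficient and returns the flagged ones
#' (class other than `"none"`) as a report table: drugs first and covariates
#' separately below, strong classes before light ones, descending posterior
#' median within class. Columns `bold_ci50`/`bold_ci90` flag intervals that
#' exclude zero (the analogue of bold display in a report).
#'
#' @param summaries A tibble of coefficient summaries as returned by
#'   [tidy.adr_fit()] (columns `term`, `estimate`, `ci50_lo`, `ci50_hi`,
#'   `ci90_lo`, `ci90_hi`, and optionally `role`). The intercept row, if
#'   present, is dropped.
#' @param keep_all Keep unflagged (`"none"`) rows too (default `FALSE`).
#' @return A tibble of class `adr_signal_table`.
#' @export
build_signal_table <- function(summaries, keep_all = FALSE) {
  tab <- tibble::as_tibble(summaries)
  if (!"role" %in% names(tab)) {
    tab$role <- ifelse(
      tab$term %in% covariate_names(), "covariate", "drug"
    )
  }
  tab <- dplyr::filter(tab, .data$role != "intercept")
  tab$class <- classify_signal(
    tab$ci50_lo, tab$ci50_hi, tab$ci90_lo, tab$ci90_hi
  )
  tab$bold_ci50 <- tab$ci50_lo > 0 | tab$ci50_hi < 0
  tab$bold_ci90 <- tab$ci90_lo > 0 | tab$ci90_hi < 0
  if (!keep_all) tab <- dplyr::filter(tab, .data$class != "none")
  tab <- tab |>
    dplyr::mutate(
      .role_ord = match(.data$role, c("drug", "covariate")),
      .class_ord = match(.data$class, signal_class_levels())
    ) |>
    dplyr::arrange(.data$.role_ord, .data$.class_ord, dplyr::desc(.data$estimate)) |>
    dplyr::select(-".role_ord", -".class_ord")
  class(tab) <- c("adr_signal_table", class(tab))
  tab
}

#' Forest plot of posterior coefficient intervals
#'
#' One row per predictor with a thick segment for the 50% credible interval,
#' a thin segment for the 90% interval, a point at the posterior median, and
#' a reference line at zero. Rows appear in the order of the input (top to
#' bottom), so the layout is deterministic given the input.
#'
#' @param summaries A tibble of coefficient summaries (see
#'   [build_signal_table()] / [tidy.adr_fit()]); must have at least one row.
#' @param outcome_label Plot title, e.g. the ADR analyzed.
#' @return A `ggplot` object.
#' @export
plot_forest <- function(summaries, outcome_label = "") {
  if (nrow(summaries) == 0) abort("Need at least one coefficient summary.")
  df <- tibble::as_tibble(summaries)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "black") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$ci90_lo, xend = .data$ci90_hi, yend = .data$term),
      linewidth = 0.4
    ) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$ci50_lo, xend = .data$ci50_hi, yend = .data$term),
      linewidth = 1.6
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate), size = 1.2) +
    ggplot2::labs(
      x = "posterior coefficient (log-odds)", y = NULL,
      title = outcome_label
    ) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @rdname plot_forest
#' @param object An `adr_signal_table`.
#' @param ... Passed to [plot_forest()].
#' @export
autoplot.adr_signal_table <- function(object, ...) {
  plot_forest(object, ...)
}

#' Save a forest plot as deterministic vector output
#'
#' Renders the plot to an SVG file via the cairo device; identical input
#' yields byte-identical output.
#'
#' @param plot A `ggplot` object.
#' @param path Output file path (`.svg`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
save_forest_plot <- function(plot, path, width = 7, height = NULL) {
  n_rows <- nrow(plot$data)
  height <- height %||% max(2, 0.6 + 0.16 * n_rows)
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
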