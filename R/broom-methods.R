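#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a summary table or audit result
#'
#' `tidy()` on a `ctdash_summary` returns one row per (metric, group) with
#' the point estimate and interval; on a `ctdash_audit` it returns the same
#' for the full run. `glance()` gives a one-row overview: cohort size,
#' metrics computed, and the cross-institution spread of the headline
#' 2-year reporting metric (when per-institution rows exist).
#'
#' @param x A `ctdash_summary` or `ctdash_audit` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ctdash_summary <- function(x, ...) {
  tibble::as_tibble(x)[c("metric", "group_type", "group", "x", "n",
                         "p", "lower", "upper")]
}

#' @rdname tidy.ctdash_summary
#' @exportS3Method generics::tidy
tidy.ctdash_audit <- function(x, ...) {
  tidy(x$summaries)
}

#' @rdname tidy.ctdash_summary
#' @exportS3Method generics::glance
glance.ctdash_summary <- function(x, ...) {
  tibble(
    n_metrics = dplyr::n_distinct(x$metric),
    n_groups = nrow(x),
    n_umcs = sum(x$group_type == "umc" & x$metric == x$metric[1])
  )
}

#' @rdname tidy.ctdash_summary
#' @exportS3Method generics::glance
glance.ctdash_audit <- function(x, ...) {
  spread <- tryCatch(
    umc_distribution(dplyr::filter(x$summaries, .data$metric == "timely_2y_either")),
    error = function(e) tibble(median = NA_real_, sd = NA_real_,
                               min = NA_real_, max = NA_real_,
                               n_umcs = 0L, n_zero_denominator = 0L)
  )
  tibble(
    n_trials = x$tally$included_count,
    duplicates_removed = x$tally$duplicates_removed,
    n_excluded = sum(x$tally$excluded_by_reason$n),
    timely_2y_median = spread$median,
    timely_2y_sd = spread$sd
  )
}

#' Plot a metric summary
#'
#' Bar chart of the per-group proportions with continuity-corrected Wilson
#' interval whiskers; percentages on the y axis, one bar per group.
#'
#' @param object A `ctdash_summary` tibble.
#' @param metric Metric id to display (default: first present).
#' @param group_type Grouping to display (default `"umc"` when present).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ctdash_summary <- function(object, metric = NULL, group_type = NULL, ...) {
  metric <- metric %||% object$metric[1]
  group_type <- group_type %||%
    (if ("umc" %in% object$group_type) "umc" else object$group_type[1])
  rows <- object |>
    dplyr::filter(.data$metric == !!metric, .data$group_type == !!group_type,
                  !is.na(.data$p))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$group, y = .data$p)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), width = 0.3
    ) +
    ggplot2::scale_y_continuous(labels = function(v) paste0(round(100 * v), "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(
      title = metric_labels()[[metric]],
      x = NULL, y = "share of trials (95% CI)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a metric's time trend
#'
#' @param summaries A `ctdash_summary` with per-year rows.
#' @param metric Metric id.
#' @return A ggplot object.
#' @export
plot_metric_trend <- function(summaries, metric) {
  rows <- summaries |>
    dplyr::filter(.data$metric == !!metric, .data$group_type == "year",
                  !is.na(.data$p)) |>
    dplyr::mutate(year = as.integer(.data$group))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$year, y = .data$p)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "#2c7fb8", alpha = 0.2) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(v) paste0(round(100 * v), "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(title = metric_labels()[[metric]], x = NULL,
                  y = "share of trials (95% CI)") +
    ggplot2::theme_minimal()
}
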