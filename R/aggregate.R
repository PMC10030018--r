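#' Continuity-corrected Wilson confidence interval
#'
#' Two-sided score interval for a binomial proportion with Yates continuity
#' correction (Newcombe's method 4). With `p = x/n`, `q = 1 - p` and `z`
#' the two-sided normal critical value,
#' \deqn{L = \frac{2x + z^2 - 1 - z\sqrt{z^2 - 2 - 1/n + 4p(nq + 1)}}{2(n + z^2)}}
#' \deqn{U = \frac{2x + z^2 + 1 + z\sqrt{z^2 + 2 - 1/n + 4p(nq - 1)}}{2(n + z^2)}}
#' clipped to `[0, 1]`, with `L = 0` when `x = 0` and `U = 1` when `x = n`.
#' The correction widens the plain Wilson interval, which matters at small
#' `n` and extreme rates (e.g. 0/44 has upper bound 10%, not the plain
#' Wilson 8%).
#'
#' @param x Successes (vectorized).
#' @param n Denominator, `n >= 1`.
#' @param level Confidence level (default 0.95, `z = 1.959964`).
#' @return Tibble with columns `x`, `n`, `p`, `lower`, `upper`, `level`,
#'   `method` (`"wilson_cc"`).
#' @examples
#' wilson_cc_interval(19, 24)
#' @export
wilson_cc_interval <- function(x, n, level = 0.95) {
  sizes <- vctrs::vec_recycle_common(x = x, n = n)
  x <- sizes$x
  n <- sizes$n
  if (any(n < 1, na.rm = TRUE)) {
    abort("proportion undefined: `n` must be >= 1")
  }
  if (any(x < 0 | x > n, na.rm = TRUE)) {
    abort("`x` must satisfy 0 <= x <= n")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  q <- 1 - p
  lower <- (2 * x + z^2 - 1 - z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * q + 1))) /
    (2 * (n + z^2))
  upper <- (2 * x + z^2 + 1 + z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * q - 1))) /
    (2 * (n + z^2))
  lower <- dplyr::if_else(x == 0, 0, pmax(0, lower))
  upper <- dplyr::if_else(x == n, 1, pmin(1, upper))
  tibble(x = x, n = n, p = p, lower = lower, upper = upper,
         level = level, method = "wilson_cc")
}

#' Identifiers of the transparency metrics the pipeline computes
#' @return Character vector of metric ids.
#' @export
metric_ids <- function() {
  c(
    "prospective", "trn_in_abstract", "trn_in_full_text", "trn_in_both",
    "link_in_registry", "summary_results",
    "timely_2y_summary", "timely_2y_publication", "timely_2y_either",
    "timely_5y_summary", "timely_5y_publication", "timely_5y_either",
    "openly_accessible"
  )
}

# per-year series use the year that drives the practice: registration is a
# property of the trial's start, OA of the publication, the rest of completion
metric_year_key <- function(metric) {
  dplyr::case_when(
    metric == "prospective" ~ "start_year",
    metric == "openly_accessible" ~ "publication_year",
    TRUE ~ "completion_year"
  )
}

metric_flag <- function(assessments, metric) {
  if (metric == "openly_accessible") {
    oa <- assessments$oa
    dplyr::if_else(is.na(oa), NA, oa != "closed")
  } else {
    assessments[[metric]]
  }
}

#' Aggregate a transparency metric into grouped proportions
#'
#' Counts `TRUE` flags over non-`NA` flags (the metric's own denominator)
#' within each group and attaches the continuity-corrected Wilson interval.
#' One row per group value plus one pooled `"all"` row; groups with an
#' empty denominator are kept with an undefined proportion so downstream
#' plots can show gaps. For `group_by = "umc"` a trial led by several
#' institutions counts once per institution, while the pooled row counts
#' each trial once.
#'
#' @param assessments Output of [assess_trials()].
#' @param metric A metric id from `metric_ids()`, e.g. `"prospective"`,
#'   `"trn_in_abstract"`, `"timely_2y_either"`, `"openly_accessible"`.
#' @param group_by `"all"`, `"umc"`, `"year"` or `"registry"`.
#' @param level Confidence level.
#' @return A `ctdash_summary` tibble: `metric`, `group_type`, `group`, `x`,
#'   `n`, `p`, `lower`, `upper`.
#' @export
aggregate_metric <- function(assessments, metric,
                             group_by = c("all", "umc", "year", "registry"),
                             level = 0.95) {
  group_by <- rlang::arg_match(group_by)
  if (!metric %in% metric_ids()) {
    abort(glue::glue("unknown metric id: {metric}"))
  }
  flag <- metric_flag(assessments, metric)
  group <- switch(group_by,
    all = rep("all", nrow(assessments)),
    umc = NULL, # handled below: requires unnesting
    year = as.character(assessments[[metric_year_key(metric)]]),
    registry = assessments$registry
  )
  tally_one <- function(f) {
    n <- sum(!is.na(f))
    x <- sum(f, na.rm = TRUE)
    if (n == 0) {
      tibble(x = 0L, n = 0L, p = NA_real_, lower = NA_real_, upper = NA_real_)
    } else {
      wilson_cc_interval(x, n, level)[c("x", "n", "p", "lower", "upper")]
    }
  }
  pooled <- tally_one(flag) |>
    dplyr::mutate(metric = metric, group_type = "all", group = "all",
                  .before = 1)
  per_group <- if (group_by == "all") {
    NULL
  } else if (group_by == "umc") {
    tibble(
      umc = unlist(assessments$lead_umcs),
      flag = rep(flag, lengths(assessments$lead_umcs))
    ) |>
      dplyr::group_by(.data$umc) |>
      dplyr::group_modify(~ tally_one(.x$flag)) |>
      dplyr::ungroup() |>
      dplyr::rename(group = "umc") |>
      dplyr::mutate(metric = metric, group_type = "umc", .before = 1)
  } else {
    tibble(group = group, flag = flag) |>
      dplyr::filter(!is.na(.data$group)) |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(~ tally_one(.x$flag)) |>
      dplyr::ungroup() |>
      dplyr::mutate(metric = metric, group_type = group_by, .before = 1)
  }
  out <- dplyr::bind_rows(per_group, pooled) |>
    dplyr::arrange(.data$group_type, .data$group)
  class(out) <- c("ctdash_summary", class(out))
  out
}

#' Summaries for every metric and grouping
#'
#' Convenience wrapper running [aggregate_metric()] over all metric ids and
#' the groupings each view needs.
#'
#' @param assessments Output of [assess_trials()].
#' @param groupings Character vector of group types.
#' @param level Confidence level.
#' @return One bound `ctdash_summary` tibble.
#' @export
aggregate_all_metrics <- function(assessments,
                                  groupings = c("all", "umc", "year", "registry"),
                                  level = 0.95) {
  groupings <- setdiff(unique(c(groupings, "all")), character())
  out <- purrr::map_dfr(metric_ids(), function(m) {
    purrr::map_dfr(setdiff(groupings, "all"), function(g) {
      aggregate_metric(assessments, m, g, level) |>
        dplyr::filter(.data$group_type != "all")
    }) |>
      dplyr::bind_rows(aggregate_metric(assessments, m, "all", level))
  }) |>
    dplyr::distinct(.data$metric, .data$group_type, .data$group, .keep_all = TRUE)
  class(out) <- c("ctdash_summary", class(out))
  out
}

#' Spread of a metric across institutions
#'
#' Median, sample standard deviation (n-1), minimum and maximum of the
#' per-institution point estimates. Institutions with an empty denominator
#' carry no rate and are excluded but counted.
#'
#' @param summaries A `ctdash_summary` tibble with per-UMC rows
#'   (`group_type == "umc"`).
#' @return One-row tibble: `median`, `sd`, `min`, `max`, `n_umcs`,
#'   `n_zero_denominator`.
#' @export
umc_distribution <- function(summaries) {
  umc_rows <- dplyr::filter(summaries, .data$group_type == "umc")
  if (nrow(umc_rows) == 0) {
    abort("no per-UMC summaries supplied")
  }
  rates <- umc_rows$p
  defined <- !is.na(rates)
  if (!any(defined)) {
    abort("no UMC has a defined proportion")
  }
  rates <- rates[defined]
  sd_val <- if (length(rates) == 1) {
    warn("only one UMC with a defined rate; standard deviation set to 0")
    0
  } else {
    stats::sd(rates)
  }
  tibble(
    median = stats::median(rates),
    sd = sd_val,
    min = min(rates),
    max = max(rates),
    n_umcs = length(rates),
    n_zero_denominator = sum(!defined)
  )
}

#' Export summaries as tidy CSV
#'
#' Writes the flat file consumed by the dashboard and by downstream users:
#' one row per (metric, group), with the percentage and interval bounds
#' rounded to integer percent the way they are displayed.
#'
#' @param summaries A `ctdash_summary` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  out <- summaries |>
    dplyr::mutate(
      year = dplyr::if_else(.data$group_type == "year", .data$group, NA_character_),
      percent = dplyr::if_else(is.na(.data$p), NA_integer_, percent_round(.data$p)),
      ci_low = dplyr::if_else(is.na(.data$lower), NA_integer_, percent_round(.data$lower)),
      ci_high = dplyr::if_else(is.na(.data$upper), NA_integer_, percent_round(.data$upper))
    ) |>
    dplyr::select("metric", "group_type", "group", "year", "x", "n",
                  "percent", "ci_low", "ci_high")
  readr::write_csv(out, path, na = "")
  invisible(path)
}
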