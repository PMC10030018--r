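#' Follow-up context for timeliness metrics
#'
#' The timeliness metrics are conditional on enough follow-up having elapsed
#' between trial completion and the observation dates: the registry download
#' date for the summary-results route and the manual publication-search date
#' for the publication route. Both must be day-resolved.
#'
#' @param registry_download_date,publication_search_date ISO-8601 date
#'   strings or `Date`s.
#' @return A `followup_context` list with two `partial_date` fields.
#' @export
followup_context <- function(registry_download_date = "2022-11-01",
                             publication_search_date = "2022-02-15") {
  ctx <- list(
    registry_download_date = parse_partial_date(registry_download_date),
    publication_search_date = parse_partial_date(publication_search_date)
  )
  ok <- vapply(ctx, function(d) identical(granularity(d), "day"), logical(1))
  if (!all(ok)) {
    abort("follow-up context dates must be day-resolved")
  }
  structure(ctx, class = "followup_context")
}

#' Was a trial registered prospectively?
#'
#' A trial is prospectively registered when its registration falls in the
#' same or an earlier calendar month than its start. The comparison is
#' month-granular; if either date lacks a month the outcome is `NA` (the
#' trial drops out of the metric's denominator), never a guess.
#'
#' @param registration_date,start_date `partial_date` vectors.
#' @return Logical vector (`NA` = not assessable).
#' @export
is_prospectively_registered <- function(registration_date, start_date) {
  cmp <- compare_month(registration_date, start_date)
  dplyr::case_when(
    cmp == "undetermined" ~ NA,
    cmp %in% c("before", "same") ~ TRUE,
    TRUE ~ FALSE
  )
}

#' Does the registration carry summary results?
#'
#' ClinicalTrials.gov exposes a structured summary-results field; DRKS has
#' none, so summary results are detected from reference titles containing a
#' results-report keyword ("Ergebnisbericht", "Abschlussbericht" by
#' default; case-insensitive substring, extensible because the registry's
#' wording is not fixed).
#'
#' @param trials Canonical trial tibble.
#' @param keywords DRKS reference-title keywords.
#' @return Logical vector, one element per trial (never `NA`: the metric's
#'   denominator is the whole cohort).
#' @export
has_summary_results <- function(trials,
                                keywords = c("ergebnisbericht", "abschlussbericht")) {
  kw <- tolower(keywords)
  vapply(seq_len(nrow(trials)), function(i) {
    if (trials$registry[i] == "ctgov") {
      isTRUE(trials$has_structured_summary_results[i])
    } else {
      titles <- tolower(trials$references[[i]]$title)
      titles <- titles[!is.na(titles)]
      any(vapply(kw, function(k) any(grepl(k, titles, fixed = TRUE)), logical(1)))
    }
  }, logical(1))
}

report_routes <- c("summary", "publication", "either")

# date on which the route's report became available; NA when the route has
# no report (incl. dissertation-only publications)
route_report_date_one <- function(trial, has_summary, pub) {
  summary_date <- if (has_summary && !is.na(trial$summary_results_date)) {
    trial$summary_results_date
  } else {
    pd_na()
  }
  pub_date <- if (!is.null(pub) && nrow(pub) == 1 && !isTRUE(pub$is_dissertation)) {
    pub$publication_date
  } else {
    pd_na()
  }
  list(summary = summary_date, publication = pub_date)
}

#' Is a trial eligible for a timeliness denominator?
#'
#' A trial enters the N-year timeliness denominator for a route only when N
#' whole years fit between its completion and the route's observation date:
#' the registry download date (summary route), the publication search date
#' (publication route), or both (either route). Month-resolved completion
#' dates are day-imputed to the first of the month before adding years;
#' year-only completion dates are not assessable and yield `FALSE`.
#'
#' @param completion_date `partial_date` vector.
#' @param route One of `"summary"`, `"publication"`, `"either"`.
#' @param years Follow-up window in years (2 or 5).
#' @param ctx A [followup_context()].
#' @return Logical vector.
#' @export
is_eligible_for_followup <- function(completion_date, route, years,
                                     ctx = followup_context()) {
  route <- rlang::arg_match(route, report_routes)
  deadline <- pd_plus_years(completion_date, years)
  dl <- pd_as_date(ctx$registry_download_date)
  search <- pd_as_date(ctx$publication_search_date)
  ok_summary <- !is.na(deadline) & deadline <= dl
  ok_pub <- !is.na(deadline) & deadline <= search
  switch(route,
    summary = ok_summary,
    publication = ok_pub,
    either = ok_summary & ok_pub
  )
}

#' Open-access status hierarchy
#'
#' @return The status labels in descending order of the assignment
#'   hierarchy: gold, hybrid, green, bronze, closed.
#' @export
oa_levels <- function() c("gold", "hybrid", "green", "bronze", "closed")

#' Classify open-access status from location evidence
#'
#' Each open-access location maps to a candidate status — an article in a
#' fully open-access journal is gold; openly licensed on the publisher page
#' of a subscription journal, hybrid; a repository copy, green; free on the
#' publisher page without a clear open license, bronze — and the
#' publication receives the highest candidate in the descending hierarchy
#' gold > hybrid > green > bronze > closed. No locations means closed. The
#' result does not depend on the order of the evidence rows.
#'
#' @param evidence Tibble with columns `host_type` (`"publisher"` or
#'   `"repository"`), `journal_is_oa`, `license_open` (logical). Zero rows
#'   allowed.
#' @return Length-1 factor over [oa_levels()].
#' @export
classify_oa_status <- function(evidence) {
  lv <- oa_levels()
  if (is.null(evidence) || nrow(evidence) == 0) {
    return(factor("closed", levels = lv))
  }
  check_columns(evidence, c("host_type", "journal_is_oa", "license_open"),
                "OA evidence")
  bad <- !evidence$host_type %in% c("publisher", "repository")
  if (any(bad)) {
    abort(glue::glue(
      "unknown host_type: {paste(unique(evidence$host_type[bad]), collapse = ', ')}"
    ))
  }
  candidate <- dplyr::case_when(
    evidence$host_type == "publisher" & isTRUE_v(evidence$journal_is_oa) ~ "gold",
    evidence$host_type == "publisher" & isTRUE_v(evidence$license_open) ~ "hybrid",
    evidence$host_type == "repository" ~ "green",
    TRUE ~ "bronze"
  )
  factor(lv[min(match(candidate, lv))], levels = lv)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Open-access status with the metric's sample rule
#'
#' The OA metric covers publications with a DOI and a dated record in the
#' open-access evidence source; otherwise the status is `NA` (out of
#' sample), not closed.
#'
#' @param pub One-row publication tibble.
#' @param oa_record List with `unpaywall_date` and `evidence` (tibble of
#'   locations), or `NULL` when the publication has no record.
#' @return Length-1 factor over [oa_levels()], or `NA`.
#' @export
oa_metric_sample <- function(pub, oa_record) {
  na_status <- factor(NA_character_, levels = oa_levels())
  if (is.na(pub$doi)) {
    return(na_status)
  }
  if (is.null(oa_record) || is.na(oa_record$unpaywall_date)) {
    return(na_status)
  }
  classify_oa_status(oa_record$evidence)
}

#' Read open-access evidence
#'
#' One row per open-access location: `pub_id`, `unpaywall_date`,
#' `host_type`, `journal_is_oa`, `license_open`. A publication with a dated
#' record but no locations appears as a row with empty `host_type`.
#' Alternatively (mode `"status"`) a two-column file `pub_id`, `oa_status`
#' is accepted verbatim for precomputed statuses.
#'
#' @param path CSV or JSON-lines file.
#' @param mode `"locations"` (default) or `"status"`.
#' @return For `"locations"`: a named list (by `pub_id`) of records with
#'   `unpaywall_date` and `evidence`. For `"status"`: a tibble `pub_id`,
#'   `oa_status`.
#' @export
read_oa_evidence <- function(path, mode = c("locations", "status")) {
  mode <- rlang::arg_match(mode)
  raw <- read_records(path)
  if (mode == "status") {
    check_columns(raw, c("pub_id", "oa_status"), "OA status file")
    bad <- !raw$oa_status %in% oa_levels()
    if (any(bad)) {
      abort(glue::glue(
        "unknown oa_status value(s): {paste(unique(raw$oa_status[bad]), collapse = ', ')}"
      ))
    }
    return(tibble(pub_id = as.character(raw$pub_id),
                  oa_status = factor(raw$oa_status, levels = oa_levels())))
  }
  check_columns(raw, c("pub_id", "unpaywall_date"), "OA evidence file")
  get <- function(col) if (col %in% names(raw)) raw[[col]] else rep(NA, nrow(raw))
  rows <- tibble(
    pub_id = as.character(raw$pub_id),
    unpaywall_date = as.character(raw$unpaywall_date),
    host_type = as.character(get("host_type")),
    journal_is_oa = as_flag(get("journal_is_oa")),
    license_open = as_flag(get("license_open"))
  )
  split(rows, rows$pub_id) |>
    purrr::map(function(g) {
      ev <- g[!is.na(g$host_type) & nzchar(g$host_type),
              c("host_type", "journal_is_oa", "license_open")]
      list(
        unpaywall_date = if (any(!is.na(g$unpaywall_date) & nzchar(g$unpaywall_date))) {
          g$unpaywall_date[[1]]
        } else {
          NA_character_
        },
        evidence = ev
      )
    })
}

#' Assess every transparency practice for a cohort
#'
#' Composes the per-trial metrics into one assessment row per trial. Each
#' metric is populated under its own denominator rule: a flag is `NA`
#' exactly when the trial (or its publication) falls outside that metric's
#' sample, so aggregation can use "non-`NA`" as the denominator throughout.
#'
#' @param trials Canonical trial tibble, filtered and deduplicated.
#' @param publications Tibble from [read_publications()].
#' @param links Trial-publication mapping (earliest results publication per
#'   trial).
#' @param oa OA evidence from [read_oa_evidence()] (either mode), or `NULL`.
#' @param ctx A [followup_context()].
#' @param drks_keywords Keywords for DRKS summary-results detection.
#' @param patterns TRN pattern inventory.
#' @return A `ctdash_assessments` tibble: identifiers and year keys plus
#'   `prospective`, `summary_results`, `trn_in_abstract`,
#'   `trn_in_full_text`, `trn_in_both`, `link_in_registry`,
#'   `timely_{2,5}y_{summary,publication,either}` and `oa`.
#' @export
assess_trials <- function(trials, publications, links, oa = NULL,
                          ctx = followup_context(),
                          drks_keywords = c("ergebnisbericht", "abschlussbericht"),
                          patterns = trn_patterns()) {
  link_flags <- assess_trn_links(trials, publications, links, patterns)
  summary_flag <- has_summary_results(trials, drks_keywords)
  pub_by_id <- split(publications, publications$pub_id)
  link_by_trn <- stats::setNames(links$pub_id, links$trn)
  oa_status_tbl <- if (is.data.frame(oa)) oa else NULL
  oa_records <- if (!is.data.frame(oa)) oa else NULL

  rows <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    trial <- trials[i, ]
    pub_id <- unname(link_by_trn[trial$trn])
    pub <- if (!is.null(pub_id) && !is.na(pub_id)) pub_by_id[[pub_id]][1, ] else NULL
    dates <- route_report_date_one(trial, summary_flag[i], pub)

    timely <- function(years, route) {
      if (!is_eligible_for_followup(trial$completion_date, route, years, ctx)) {
        return(NA)
      }
      rd <- route_report_date(dates$summary, dates$publication, route)
      deadline <- pd_plus_years(trial$completion_date, years)
      !is.na(rd) && !is.na(pd_as_date(rd)) && pd_as_date(rd) <= deadline
    }

    oa_status <- factor(NA_character_, levels = oa_levels())
    if (!is.null(pub) && !isTRUE(pub$is_dissertation)) {
      if (!is.null(oa_status_tbl)) {
        hit <- match(pub$pub_id, oa_status_tbl$pub_id)
        if (!is.na(hit) && !is.na(pub$doi)) {
          oa_status <- oa_status_tbl$oa_status[hit]
        }
      } else {
        oa_status <- oa_metric_sample(pub, oa_records[[pub$pub_id]])
      }
    }

    tibble(
      trn = trial$trn,
      registry = trial$registry,
      lead_umcs = list(trial$lead_umcs[[1]]),
      start_year = pd_year(trial$start_date),
      completion_year = pd_year(trial$completion_date),
      publication_year = if (!is.null(pub) && !isTRUE(pub$is_dissertation)) {
        pd_year(pub$publication_date)
      } else {
        NA_integer_
      },
      prospective = if (is.na(pd_month(trial$start_date))) {
        NA
      } else {
        is_prospectively_registered(trial$registration_date, trial$start_date)
      },
      summary_results = summary_flag[i],
      timely_2y_summary = timely(2, "summary"),
      timely_2y_publication = timely(2, "publication"),
      timely_2y_either = timely(2, "either"),
      timely_5y_summary = timely(5, "summary"),
      timely_5y_publication = timely(5, "publication"),
      timely_5y_either = timely(5, "either"),
      oa = oa_status
    )
  })
  out <- dplyr::left_join(
    rows,
    link_flags[c("trn", "trn_in_abstract", "trn_in_full_text", "trn_in_both",
                 "publication_linked_in_registry")],
    by = "trn"
  ) |>
    dplyr::rename(link_in_registry = "publication_linked_in_registry")
  class(out) <- c("ctdash_assessments", class(out))
  out
}

#' Report date for a reporting route
#'
#' The summary route reports on the registry's summary-results date, the
#' publication route on the linked earliest non-dissertation publication's
#' date, and the either route on whichever came first; `NA` when the route
#' has no report.
#'
#' @param summary_date,publication_date `partial_date` scalars (already
#'   resolved per trial; `NA` when the route has no report).
#' @param route One of `"summary"`, `"publication"`, `"either"`.
#' @return A `partial_date` scalar.
#' @export
route_report_date <- function(summary_date, publication_date,
                              route = c("summary", "publication", "either")) {
  route <- rlang::arg_match(route)
  if (route == "summary") {
    return(summary_date)
  }
  if (route == "publication") {
    return(publication_date)
  }
  s <- pd_as_date(summary_date)
  p <- pd_as_date(publication_date)
  if (is.na(s)) {
    return(publication_date)
  }
  if (is.na(p)) {
    return(summary_date)
  }
  if (s <= p) summary_date else publication_date
}
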