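metric_labels <- function() {
  c(
    prospective = "Prospective registration",
    trn_in_abstract = "TRN reported in abstract",
    trn_in_full_text = "TRN reported in full text",
    trn_in_both = "TRN reported in abstract and full text",
    link_in_registry = "Publication linked in the registry",
    summary_results = "Summary results in the registry",
    timely_2y_summary = "Summary results within 2 years",
    timely_2y_publication = "Publication within 2 years",
    timely_2y_either = "Results reported within 2 years",
    timely_5y_summary = "Summary results within 5 years",
    timely_5y_publication = "Publication within 5 years",
    timely_5y_either = "Results reported within 5 years",
    openly_accessible = "Openly accessible publication"
  )
}

#' Per-metric method and limitation notes
#'
#' Short plain-language descriptions shown next to each dashboard plot:
#' what the metric measures, its denominator and its main caveat.
#'
#' @return Tibble with columns `metric`, `label`, `methods`, `limitations`.
#' @export
metric_descriptions <- function() {
  tibble(
    metric = names(metric_labels()),
    label = unname(metric_labels()),
    methods = c(
      "A trial counts as prospectively registered when registered in the same or an earlier calendar month than its start date; the comparison is month-granular. Denominator: trials with a start date in the registry.",
      "Regular-expression detection of the trial's registration number (or a known cross-registration) in the publication abstract. Denominator: trials with a non-dissertation publication that has a PubMed identifier and an abstract.",
      "Registration-number detection over the retrieved plain full text. Denominator: trials with a non-dissertation publication whose full text was retrieved.",
      "The trial's registration number was detected in both abstract and full text. Denominator: trials where both constituent checks were assessable.",
      "The earliest results publication's DOI or PMID appears among the registration's references. Denominator: trials with a non-dissertation publication carrying a DOI or PMID.",
      "ClinicalTrials.gov: structured summary-results field. DRKS: a registry reference titled with a results-report keyword. Denominator: all cohort trials.",
      "Summary results posted within 2 years of completion; only trials whose 2-year window closed before the registry download date count.",
      "A non-dissertation results publication within 2 years of completion; only trials whose 2-year window closed before the publication search date count.",
      "Results available via either route within 2 years; both follow-up windows must have closed.",
      "Summary results posted within 5 years of completion; 5-year window closed before the registry download date.",
      "A results publication within 5 years of completion; 5-year window closed before the publication search date.",
      "Results available via either route within 5 years; both follow-up windows must have closed.",
      "Open-access status from location evidence under the descending hierarchy gold, hybrid, green, bronze, closed; 'open' means any status above closed. Denominator: publications with a DOI and a dated open-access record."
    ),
    limitations = c(
      "Relies on registry dates being accurate; month granularity cannot resolve same-month ties further.",
      "Abstract text availability varies; identifiers written in unusual formats may escape the patterns.",
      "Full-text retrieval is incomplete and text extraction quality varies.",
      "Inherits the limitations of both constituent checks.",
      "Registry reference lists may lag behind actual publications.",
      "Keyword detection for DRKS may miss unusually titled result reports.",
      "Registry summary-results dates may be entered late.",
      "Publication dates reflect the earliest identified publication, which may not be the first public report.",
      "Combines the caveats of both reporting routes.",
      "Registry summary-results dates may be entered late.",
      "Publication dates reflect the earliest identified publication.",
      "Combines the caveats of both reporting routes.",
      "Open-access evidence reflects one snapshot; statuses change over time."
    )
  )
}

#' Assemble the dashboard dataset
#'
#' Bundles the grouped summaries into the three report views — pooled
#' across institutions, comparative between institutions, and one page per
#' institution — plus the EU-tracker series and a provenance block
#' (configuration snapshot, input digests, dates) so every export is a
#' dated, reproducible snapshot.
#'
#' @param summaries A `ctdash_summary` tibble covering at least the `umc`
#'   and `all` groupings.
#' @param tracker Tibble from [read_euctr_tracker_history()], or `NULL`.
#' @param provenance Named list (free-form) recorded verbatim.
#' @return A `dashboard_dataset` list with elements `metrics`,
#'   `all_umc_page`, `umc_pages`, `euctr_series`, `provenance`.
#' @export
build_dashboard_dataset <- function(summaries, tracker = NULL,
                                    provenance = list()) {
  if (nrow(summaries) == 0) {
    abort("`summaries` must be non-empty")
  }
  missing_metrics <- setdiff(metric_ids(), unique(summaries$metric))
  if (length(missing_metrics) > 0) {
    warn(glue::glue(
      "no summaries for metric(s): {paste(missing_metrics, collapse = ', ')}; ",
      "pages will show gaps"
    ))
  }
  umcs <- summaries |>
    dplyr::filter(.data$group_type == "umc") |>
    dplyr::pull(.data$group) |>
    unique() |>
    sort()
  umc_pages <- purrr::map(umcs, function(u) {
    list(
      umc = u,
      metrics = dplyr::filter(summaries, .data$group_type == "umc", .data$group == u),
      euctr = if (!is.null(tracker)) {
        dplyr::filter(tracker, .data$sponsor_name == u)
      } else {
        NULL
      }
    )
  })
  names(umc_pages) <- umcs
  structure(
    list(
      metrics = summaries,
      all_umc_page = dplyr::filter(summaries, .data$group_type != "umc"),
      umc_pages = umc_pages,
      euctr_series = tracker,
      provenance = provenance
    ),
    class = "dashboard_dataset"
  )
}

#' Serialize / deserialize a dashboard dataset as JSON
#'
#' @param ds A `dashboard_dataset`.
#' @param path Output (input) JSON path.
#' @return `path` invisibly (`read_dashboard_json()` returns the dataset).
#' @export
write_dashboard_json <- function(ds, path) {
  stopifnot(inherits(ds, "dashboard_dataset"))
  payload <- list(
    metrics = summary_for_json(ds$metrics),
    euctr_series = if (!is.null(ds$euctr_series)) {
      dplyr::mutate(ds$euctr_series, snapshot_date = format(.data$snapshot_date))
    } else {
      NULL
    },
    provenance = ds$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

summary_for_json <- function(summaries) {
  as.data.frame(summaries[c("metric", "group_type", "group", "x", "n",
                            "p", "lower", "upper")])
}

#' @rdname write_dashboard_json
#' @export
read_dashboard_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  summaries <- tibble::as_tibble(payload$metrics)
  class(summaries) <- c("ctdash_summary", class(summaries))
  tracker <- if (!is.null(payload$euctr_series)) {
    tibble::as_tibble(payload$euctr_series) |>
      dplyr::mutate(snapshot_date = parse_partial_date(.data$snapshot_date))
  } else {
    NULL
  }
  build_dashboard_dataset(summaries, tracker, payload$provenance)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# one horizontal bar per row; absolute numbers ride along as <title>
# tooltips so every displayed percentage is backed by its x/n
svg_bar_chart <- function(rows, label_col = "group") {
  if (nrow(rows) == 0 || all(is.na(rows$p))) {
    return("<p class='placeholder'>no data</p>")
  }
  bar_h <- 22
  width <- 640
  label_w <- 180
  h <- bar_h * nrow(rows) + 10
  bars <- purrr::map_chr(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    y <- (i - 1) * bar_h + 5
    pct <- if (is.na(r$p)) NA else percent_round(r$p)
    tip <- if (is.na(r$p)) {
      sprintf("%s: no trials in denominator", r[[label_col]])
    } else {
      sprintf("%s: %d%% (%d/%d), 95%% CI %d%%-%d%%",
              r[[label_col]], pct, r$x, r$n,
              percent_round(r$lower), percent_round(r$upper))
    }
    w <- if (is.na(r$p)) 0 else round((width - label_w - 60) * r$p, 1)
    glue::glue(
      '<g><title>{html_escape(tip)}</title>',
      '<text x="0" y="{y + 15}" font-size="12">{html_escape(substr(r[[label_col]], 1, 28))}</text>',
      '<rect x="{label_w}" y="{y + 3}" width="{w}" height="{bar_h - 8}" fill="#2c7fb8"></rect>',
      '<text x="{label_w + w + 4}" y="{y + 15}" font-size="12">',
      '{if (is.na(r$p)) "n/a" else paste0(pct, "% (", r$x, "/", r$n, ")")}</text></g>'
    )
  })
  glue::glue(
    '<svg width="{width}" height="{h}" xmlns="http://www.w3.org/2000/svg">',
    '{paste(bars, collapse = "")}</svg>'
  )
}

metric_panel <- function(summaries, metric, group_type) {
  desc <- dplyr::filter(metric_descriptions(), .data$metric == !!metric)
  rows <- summaries |>
    dplyr::filter(.data$metric == !!metric, .data$group_type == !!group_type) |>
    dplyr::arrange(.data$group)
  glue::glue(
    "<section><h3>{html_escape(desc$label)}</h3>",
    "{svg_bar_chart(rows)}",
    "<details><summary>Methods and limitations</summary>",
    "<p>{html_escape(desc$methods)}</p>",
    "<p><em>{html_escape(desc$limitations)}</em></p></details></section>"
  )
}

html_page <- function(title, body) {
  glue::glue(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>{html_escape(title)}</title>",
    "<style>body{{font-family:sans-serif;max-width:720px;margin:2em auto}}",
    ".placeholder{{color:#888}}</style></head>",
    "<body><h1>{html_escape(title)}</h1>{body}</body></html>"
  )
}

umc_slug <- function(x) tolower(gsub("[^A-Za-z0-9]+", "-", x))

#' Report output configuration
#'
#' @param out_dir Output directory.
#' @param formats Subset of `c("csv", "json", "html")`; at least one.
#' @param include_absolute_numbers Embed absolute numerators/denominators in
#'   plot tooltips.
#' @return A `report_config` list.
#' @export
report_config <- function(out_dir, formats = c("csv", "json", "html"),
                          include_absolute_numbers = TRUE) {
  formats <- match.arg(formats, c("csv", "json", "html"), several.ok = TRUE)
  if (length(formats) == 0) {
    abort("at least one output format is required")
  }
  structure(
    list(out_dir = out_dir, formats = formats,
         include_absolute_numbers = isTRUE(include_absolute_numbers)),
    class = "report_config"
  )
}

#' Render the dashboard as a static site
#'
#' Writes self-contained HTML (no network dependency, plots as inline SVG
#' with absolute numbers in native tooltips) for the three views: pooled
#' across institutions (`index.html`), comparative (`compare.html`) and one
#' page per institution (`umc-<slug>.html`); plus the tidy CSV and nested
#' JSON exports per the configured formats. Output depends only on the
#' dataset, so identical inputs give identical files.
#'
#' @param ds A `dashboard_dataset`.
#' @param cfg A [report_config()].
#' @return Character vector of written file paths, invisibly.
#' @export
render_static_site <- function(ds, cfg) {
  stopifnot(inherits(ds, "dashboard_dataset"), inherits(cfg, "report_config"))
  ok <- dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$out_dir)) {
    abort(glue::glue("cannot create output directory {cfg$out_dir}"))
  }
  written <- character()
  if ("csv" %in% cfg$formats) {
    p <- file.path(cfg$out_dir, "summaries.csv")
    write_summary_csv(ds$metrics, p)
    written <- c(written, p)
  }
  if ("json" %in% cfg$formats) {
    p <- file.path(cfg$out_dir, "dashboard.json")
    write_dashboard_json(ds, p)
    written <- c(written, p)
  }
  if ("html" %in% cfg$formats) {
    provenance_note <- if (length(ds$provenance) > 0) {
      glue::glue(
        "<footer><small>Snapshot: {html_escape(jsonlite::toJSON(ds$provenance, auto_unbox = TRUE))}</small></footer>"
      )
    } else {
      ""
    }
    panels_all <- paste(
      purrr::map_chr(metric_ids(), ~ metric_panel(ds$metrics, .x, "all")),
      collapse = "\n"
    )
    index <- html_page("Trial transparency across all institutions",
                       paste0(panels_all, provenance_note))
    panels_cmp <- paste(
      purrr::map_chr(metric_ids(), ~ metric_panel(ds$metrics, .x, "umc")),
      collapse = "\n"
    )
    compare <- html_page("Comparative view by institution",
                         paste0(panels_cmp, provenance_note))
    paths <- c(
      index = file.path(cfg$out_dir, "index.html"),
      compare = file.path(cfg$out_dir, "compare.html")
    )
    writeLines(index, paths[["index"]])
    writeLines(compare, paths[["compare"]])
    umc_paths <- purrr::imap_chr(ds$umc_pages, function(page, u) {
      body <- paste(
        purrr::map_chr(metric_ids(), ~ metric_panel(page$metrics, .x, "umc")),
        collapse = "\n"
      )
      euctr_body <- if (!is.null(page$euctr) && nrow(page$euctr) > 0) {
        rows <- page$euctr |>
          dplyr::transmute(
            group = format(.data$snapshot_date),
            x = .data$total_reported, n = .data$total_due,
            p = .data$percent_reported / 100
          ) |>
          dplyr::mutate(ci = wilson_cc_interval(.data$x, .data$n)[c("lower", "upper")]) |>
          tidyr::unpack("ci")
        paste0("<section><h3>Summary results in the EU registry</h3>",
               svg_bar_chart(rows), "</section>")
      } else {
        "<section><h3>Summary results in the EU registry</h3><p class='placeholder'>no data</p></section>"
      }
      p <- file.path(cfg$out_dir, paste0("umc-", umc_slug(u), ".html"))
      writeLines(html_page(paste("Institution:", u),
                           paste0(body, "\n", euctr_body, provenance_note)), p)
      p
    })
    written <- c(written, paths, umc_paths)
  }
  invisible(written)
}

#' Run the full audit pipeline
#'
#' Orchestrates parse, cohort filter, cross-registration dedup, linkage,
#' metric assessment, aggregation and export, writing a line-oriented run
#' log with the exclusion tally. Input schema problems raise errors naming
#' the offending column.
#'
#' @param trials Named character vector of trial-export paths, names are
#'   dialects (e.g. `c(ctgov = "trials_ctgov.csv", drks = "trials_drks.csv")`).
#' @param publications,links,oa,tracker Input paths (latter two optional).
#' @param oa_mode `"locations"` for per-location evidence rows, `"status"`
#'   for a precomputed `oa_status` column accepted verbatim.
#' @param out_dir Output directory.
#' @param criteria [cohort_criteria()].
#' @param ctx [followup_context()].
#' @param formats Output formats for [render_static_site()].
#' @param level Confidence level.
#' @param drks_keywords DRKS summary-results keywords.
#' @return A `ctdash_audit` list with `assessments`, `summaries`,
#'   `dashboard`, `tally`, invisibly.
#' @export
run_audit <- function(trials, publications, links, oa = NULL, tracker = NULL,
                      oa_mode = c("locations", "status"),
                      out_dir, criteria = cohort_criteria(),
                      ctx = followup_context(),
                      formats = c("csv", "json", "html"), level = 0.95,
                      drks_keywords = c("ergebnisbericht", "abschlussbericht")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  trial_tbl <- purrr::imap_dfr(trials, function(path, dialect) {
    read_trials(path, dialect)
  })
  log_add("parsed ", nrow(trial_tbl), " trial records from ",
          length(trials), " file(s)")
  filtered <- apply_cohort_filters(trial_tbl, criteria)
  deduped <- deduplicate_cross_registrations(filtered)
  tally <- exclusion_tally(deduped)
  log_add("cohort filter input: ", tally$input_count)
  for (i in seq_len(nrow(tally$excluded_by_reason))) {
    log_add("excluded ", tally$excluded_by_reason$reason[i], ": ",
            tally$excluded_by_reason$n[i])
  }
  log_add("cross-registration duplicates removed: ", tally$duplicates_removed)
  log_add("included: ", tally$included_count)

  pubs <- read_publications(publications)
  link_tbl <- read_trial_publication_links(links)
  link_tbl <- dplyr::filter(link_tbl, .data$trn %in% deduped$trn)
  oa_data <- if (!is.null(oa)) read_oa_evidence(oa, rlang::arg_match(oa_mode)) else NULL
  tracker_tbl <- if (!is.null(tracker)) read_euctr_tracker_history(tracker) else NULL

  assessments <- assess_trials(deduped, pubs, link_tbl, oa_data, ctx,
                               drks_keywords)
  summaries <- aggregate_all_metrics(assessments, level = level)
  provenance <- list(
    n_trials = nrow(deduped),
    registry_download_date = format(ctx$registry_download_date),
    publication_search_date = format(ctx$publication_search_date),
    inputs = purrr::map_chr(
      purrr::compact(c(as.list(trials),
                       list(publications = publications, links = links,
                            oa = oa, tracker = tracker))),
      ~ unname(tools::md5sum(.x))
    )
  )
  ds <- build_dashboard_dataset(summaries, tracker_tbl, provenance)
  render_static_site(ds, report_config(out_dir, formats))
  writeLines(log_lines, log_path)
  out <- structure(
    list(assessments = assessments, summaries = summaries, dashboard = ds,
         tally = tally),
    class = "ctdash_audit"
  )
  invisible(out)
}
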