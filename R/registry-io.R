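#' Column-mapping profiles for registry dialects
#'
#' Flat-file exports from ClinicalTrials.gov and DRKS name the same concepts
#' differently (first-submission date vs. registration date, NCT number vs.
#' DRKS-ID). A dialect profile maps source column names onto the canonical
#' trial-record fields; profiles can be overridden from a YAML config so the
#' readers also accept preprocessed real-data exports.
#'
#' @param path Optional YAML file with a top-level `dialects:` block to merge
#'   over the built-in defaults.
#' @return Named list of dialect profiles (`ctgov`, `drks`), each a named
#'   character vector `canonical_field = source_column`.
#' @export
registry_dialects <- function(path = NULL) {
  defaults <- list(
    ctgov = c(
      trn = "nct_id",
      lead_umcs = "lead_umcs",
      start_date = "start_date",
      completion_date = "completion_date",
      registration_date = "study_first_submitted_date",
      status = "overall_status",
      study_type = "study_type",
      has_structured_summary_results = "has_summary_results",
      summary_results_date = "results_first_submitted_date",
      references = "references",
      secondary_ids = "secondary_ids"
    ),
    drks = c(
      trn = "drks_id",
      lead_umcs = "lead_umcs",
      start_date = "start_date",
      completion_date = "completion_date",
      registration_date = "registration_date",
      status = "recruitment_status",
      study_type = "study_type",
      has_structured_summary_results = "has_summary_results",
      summary_results_date = "summary_results_date",
      references = "references",
      secondary_ids = "secondary_ids"
    )
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)$dialects
    for (reg in names(user)) {
      defaults[[reg]][names(user[[reg]])] <- unlist(user[[reg]])
    }
  }
  defaults
}

trn_registry_pattern <- c(
  ctgov = "^NCT\\d{8}$",
  drks = "^DRKS\\d{8}$"
)

#' Read trial registrations into the canonical trial table
#'
#' Reads one registry export (CSV or JSON-lines, one record per row/line),
#' applies the dialect's column mapping and returns the canonical trial
#' tibble used by the rest of the pipeline. List-valued fields
#' (`lead_umcs`, `secondary_ids`) are split on `";"` in CSV input;
#' `references` is a JSON array column in CSV and a nested array in
#' JSON-lines.
#'
#' @param path CSV (`.csv`) or JSON-lines (`.jsonl`/`.ndjson`) file.
#' @param dialect `"ctgov"` or `"drks"`.
#' @param dialects Profiles from [registry_dialects()].
#' @return Tibble with columns `trn`, `registry`, `lead_umcs` (list),
#'   `start_date`, `completion_date`, `registration_date`,
#'   `summary_results_date` (all `partial_date`), `status`, `study_type`,
#'   `has_structured_summary_results`, `references` (list of tibbles),
#'   `secondary_ids` (list), `cross_registrations` (list, filled by
#'   [deduplicate_cross_registrations()]).
#' @export
read_trials <- function(path, dialect = c("ctgov", "drks"),
                        dialects = registry_dialects()) {
  dialect <- rlang::arg_match(dialect)
  raw <- read_records(path)
  map <- dialects[[dialect]]
  missing <- setdiff(unname(map), names(raw))
  # references/secondary ids may be legitimately absent from sparse exports
  optional <- map[c("references", "secondary_ids", "summary_results_date")]
  hard_missing <- setdiff(missing, unname(optional))
  if (length(hard_missing) > 0) {
    abort(glue::glue(
      "trial file {path} is missing column(s): {paste(hard_missing, collapse = ', ')}"
    ))
  }
  col <- function(field, default = NA) {
    src <- map[[field]]
    if (!is.null(src) && src %in% names(raw)) raw[[src]] else rep(default, nrow(raw))
  }
  trials <- tibble(
    trn = normalize_trn(as.character(col("trn"))),
    registry = dialect,
    lead_umcs = as_string_list(col("lead_umcs")),
    start_date = parse_partial_date(col("start_date")),
    completion_date = parse_partial_date(col("completion_date")),
    registration_date = parse_partial_date(col("registration_date")),
    status = as.character(col("status")),
    study_type = as.character(col("study_type")),
    has_structured_summary_results = as_flag(col("has_structured_summary_results", FALSE)),
    summary_results_date = parse_partial_date(col("summary_results_date")),
    references = as_reference_list(col("references")),
    secondary_ids = as_string_list(col("secondary_ids")),
    cross_registrations = purrr::map(seq_len(nrow(raw)), ~ character())
  )
  bad <- !grepl(trn_registry_pattern[[dialect]], trials$trn)
  if (any(bad)) {
    abort(glue::glue(
      "registration number(s) not in {dialect} format: ",
      "{paste(trials$trn[bad], collapse = ', ')}"
    ))
  }
  trials
}

read_records <- function(path) {
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(lines)]
    recs <- purrr::map(lines, jsonlite::fromJSON, simplifyDataFrame = TRUE)
    tibble::as_tibble(do.call(rbind.data.frame, c(
      purrr::map(recs, normalize_record), stringsAsFactors = FALSE
    )))
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
}

# flatten a parsed JSON-lines record: scalars stay, arrays re-serialized so
# both input routes hit the same list-column coercers
normalize_record <- function(rec) {
  purrr::map(rec, function(v) {
    if (is.data.frame(v) || length(v) > 1 || is.list(v)) {
      jsonlite::toJSON(v, auto_unbox = TRUE)
    } else if (length(v) == 0) {
      NA_character_
    } else {
      as.character(v)
    }
  })
}

as_flag <- function(x) {
  if (is.logical(x)) {
    return(x)
  }
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes", "y")
}

as_string_list <- function(x) {
  purrr::map(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      return(character())
    }
    if (startsWith(trimws(s), "[")) {
      as.character(unlist(jsonlite::fromJSON(s)))
    } else {
      trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    }
  })
}

empty_references <- function() {
  tibble(
    title = character(), doi = character(), pmid = character(),
    is_results_reference = logical()
  )
}

as_reference_list <- function(x) {
  purrr::map(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s)) || trimws(s) == "[]") {
      return(empty_references())
    }
    parsed <- jsonlite::fromJSON(s, simplifyDataFrame = TRUE)
    if (length(parsed) == 0) {
      return(empty_references())
    }
    refs <- tibble::as_tibble(parsed)
    for (f in c("title", "doi", "pmid")) {
      if (!f %in% names(refs)) refs[[f]] <- NA_character_
      refs[[f]] <- as.character(refs[[f]])
    }
    if (!"is_results_reference" %in% names(refs)) {
      refs$is_results_reference <- FALSE
    }
    refs$is_results_reference <- as_flag(refs$is_results_reference)
    has_any <- !is.na(refs$title) | !is.na(refs$doi) | !is.na(refs$pmid)
    if (!all(has_any)) {
      abort("every registry reference needs at least one of title, doi, pmid")
    }
    refs[c("title", "doi", "pmid", "is_results_reference")]
  })
}

#' Cohort inclusion criteria
#'
#' The audited cohort comprises interventional trials considered complete per
#' registry status with a completion date inside a fixed year window
#' (2009-2017 by default). The status strings that count as "complete" vary
#' with registry vintage, so they are a configuration knob.
#'
#' @param completion_from,completion_to First and last admissible completion
#'   year.
#' @param complete_statuses Registry status strings treated as complete.
#' @param require_interventional Keep interventional trials only.
#' @param require_start_date Also exclude trials without a start date (used
#'   for the prospective-registration sample).
#' @return A `cohort_criteria` list.
#' @export
cohort_criteria <- function(completion_from = 2009L,
                            completion_to = 2017L,
                            complete_statuses = c(
                              "Completed", "Terminated", "Suspended",
                              "Unknown status"
                            ),
                            require_interventional = TRUE,
                            require_start_date = FALSE) {
  if (completion_from > completion_to) {
    abort("`completion_from` must be <= `completion_to`")
  }
  structure(
    list(
      completion_from = as.integer(completion_from),
      completion_to = as.integer(completion_to),
      complete_statuses = complete_statuses,
      require_interventional = isTRUE(require_interventional),
      require_start_date = isTRUE(require_start_date)
    ),
    class = "cohort_criteria"
  )
}

exclusion_reasons <- c(
  "completion_date_outside_window",
  "status_not_complete",
  "not_interventional",
  "missing_start_date"
)

#' Apply the cohort inclusion/exclusion filters
#'
#' Filters run in a fixed order — (1) completion year outside the window
#' (missing completion dates fall here), (2) status not considered complete,
#' (3) study type not interventional, (4, optional) missing start date — and
#' each excluded trial is tallied under the *first* reason that removes it.
#'
#' @param trials Canonical trial tibble from [read_trials()].
#' @param criteria A [cohort_criteria()] object.
#' @return The included trials, with the exclusion tally attached as an
#'   attribute; retrieve it with [exclusion_tally()].
#' @export
apply_cohort_filters <- function(trials, criteria = cohort_criteria()) {
  stopifnot(inherits(criteria, "cohort_criteria"))
  check_columns(trials, c("completion_date", "status", "study_type"), "trial table")
  n_in <- nrow(trials)
  year <- pd_year(trials$completion_date)
  reason <- rep(NA_character_, n_in)
  out_window <- is.na(year) | year < criteria$completion_from |
    year > criteria$completion_to
  reason[out_window] <- exclusion_reasons[1]
  bad_status <- is.na(reason) & !(trials$status %in% criteria$complete_statuses)
  reason[bad_status] <- exclusion_reasons[2]
  if (criteria$require_interventional) {
    bad_type <- is.na(reason) & trials$study_type != "interventional"
    reason[bad_type] <- exclusion_reasons[3]
  }
  if (criteria$require_start_date) {
    no_start <- is.na(reason) & is.na(pd_month(trials$start_date))
    reason[no_start] <- exclusion_reasons[4]
  }
  counts <- vapply(
    exclusion_reasons, function(r) sum(reason == r, na.rm = TRUE), integer(1)
  )
  included <- trials[is.na(reason), , drop = FALSE]
  missing_completion <- sum(out_window & is.na(year))
  if (missing_completion > 0) {
    inform(glue::glue(
      "{missing_completion} trial(s) excluded with a missing completion date"
    ))
  }
  tally <- tibble(
    reason = exclusion_reasons,
    n = unname(counts)
  )
  structure_tally <- list(
    input_count = n_in,
    excluded_by_reason = tally,
    duplicates_removed = 0L,
    included_count = nrow(included)
  )
  attr(included, "exclusion_tally") <- structure_tally
  included
}

#' Retrieve the exclusion tally from a filtered trial table
#'
#' @param trials Output of [apply_cohort_filters()] (optionally after
#'   [deduplicate_cross_registrations()], which adds its duplicate count).
#' @return List with `input_count`, `excluded_by_reason` (tibble),
#'   `duplicates_removed` and `included_count`; counts always conserve:
#'   `input = included + duplicates + sum(excluded)`.
#' @export
exclusion_tally <- function(trials) {
  tally <- attr(trials, "exclusion_tally")
  if (is.null(tally)) {
    abort("no exclusion tally attached; run `apply_cohort_filters()` first")
  }
  tally
}

#' Collapse cross-registrations between ClinicalTrials.gov and DRKS
#'
#' A trial registered in both registries appears twice; the pair is detected
#' when either record's secondary identifiers contain the other's
#' registration number (after canonicalization, so spacing/hyphens/case do
#' not hide a pair). The ClinicalTrials.gov member is retained — it carries
#' the structured summary-results field used downstream — with the union of
#' both records' registry references merged onto it, and the partner number
#' recorded in `cross_registrations` so either identifier counts as the
#' trial's own in TRN detection.
#'
#' @param trials Canonical trial tibble (both registries mixed).
#' @return The deduplicated tibble; the pair log (tibble with `trn_kept`,
#'   `trn_removed`) is available via [dedup_log()] and the removed count is
#'   added to any attached exclusion tally.
#' @export
deduplicate_cross_registrations <- function(trials) {
  sec_norm <- purrr::map(trials$secondary_ids, normalize_trn)
  trn <- trials$trn
  ct_idx <- which(trials$registry == "ctgov")
  dr_idx <- which(trials$registry == "drks")
  ct_by_trn <- stats::setNames(ct_idx, trn[ct_idx])
  dr_by_trn <- stats::setNames(dr_idx, trn[dr_idx])
  # a pair exists when either member's secondary ids name the other's trn
  from_ctgov <- purrr::map(ct_idx, function(i) {
    js <- dr_by_trn[intersect(sec_norm[[i]], names(dr_by_trn))]
    if (length(js)) cbind(ctgov = i, drks = unname(js)) else NULL
  })
  from_drks <- purrr::map(dr_idx, function(j) {
    is <- ct_by_trn[intersect(sec_norm[[j]], names(ct_by_trn))]
    if (length(is)) cbind(ctgov = unname(is), drks = j) else NULL
  })
  pair_mat <- unique(do.call(rbind, c(from_ctgov, from_drks)))
  pairs <- if (is.null(pair_mat)) {
    list()
  } else {
    purrr::map(seq_len(nrow(pair_mat)), ~ pair_mat[.x, ])
  }
  if (length(pairs) == 0) {
    attr(trials, "dedup_log") <- tibble(trn_kept = character(), trn_removed = character())
    return(trials)
  }
  keep_idx <- vapply(pairs, `[[`, integer(1), "ctgov")
  drop_idx <- vapply(pairs, `[[`, integer(1), "drks")
  if (anyDuplicated(keep_idx) || anyDuplicated(drop_idx)) {
    warn("cross-registration chain detected; collapsing to one retained record")
  }
  for (k in seq_along(pairs)) {
    i <- keep_idx[k]
    j <- drop_idx[k]
    merged <- dplyr::distinct(dplyr::bind_rows(
      trials$references[[i]], trials$references[[j]]
    ))
    trials$references[[i]] <- merged
    trials$cross_registrations[[i]] <- unique(c(
      trials$cross_registrations[[i]], trn[j], trials$cross_registrations[[j]]
    ))
  }
  out <- trials[-unique(drop_idx), , drop = FALSE]
  removed <- length(unique(drop_idx))
  log <- tibble(trn_kept = trn[keep_idx], trn_removed = trn[drop_idx])
  tally <- attr(trials, "exclusion_tally")
  if (!is.null(tally)) {
    tally$duplicates_removed <- tally$duplicates_removed + removed
    tally$included_count <- tally$included_count - removed
    attr(out, "exclusion_tally") <- tally
  }
  attr(out, "dedup_log") <- log
  out
}

#' Pair log of removed cross-registrations
#' @param trials Output of [deduplicate_cross_registrations()].
#' @return Tibble with columns `trn_kept`, `trn_removed`.
#' @export
dedup_log <- function(trials) {
  log <- attr(trials, "dedup_log")
  if (is.null(log)) {
    abort("no dedup log attached; run `deduplicate_cross_registrations()` first")
  }
  log
}

#' Read EU Trials Tracker history rows
#'
#' The EU registry's summary-results rates come pass-through from the EU
#' Trials Tracker rather than being recomputed from trial records. Input is
#' a CSV (or tibble) with columns `sponsor`, `date` (ISO-8601),
#' `total_due`, `total_reported` and optionally `percent_reported`; the
#' percentage is recomputed from the counts when absent and validated
#' against them when present.
#'
#' @param x Path to a CSV file, or a data frame.
#' @return Tibble sorted by snapshot date with columns `sponsor_name`,
#'   `snapshot_date` (`partial_date`), `total_due`, `total_reported`,
#'   `percent_reported` (percent scale).
#' @export
read_euctr_tracker_history <- function(x) {
  rows <- if (is.data.frame(x)) {
    tibble::as_tibble(x)
  } else {
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  check_columns(rows, c("sponsor", "date", "total_due", "total_reported"),
                "EU Trials Tracker history")
  out <- tibble(
    sponsor_name = as.character(rows$sponsor),
    snapshot_date = parse_partial_date(rows$date),
    total_due = as.integer(rows$total_due),
    total_reported = as.integer(rows$total_reported)
  )
  bad <- out$total_reported > out$total_due
  if (any(bad)) {
    abort(glue::glue(
      "reported exceeds due for sponsor(s): ",
      "{paste(out$sponsor_name[bad], collapse = ', ')}"
    ))
  }
  pct <- if ("percent_reported" %in% names(rows)) {
    as.numeric(rows$percent_reported)
  } else {
    rep(NA_real_, nrow(out))
  }
  recomputed <- 100 * out$total_reported / out$total_due
  out$percent_reported <- dplyr::coalesce(pct, recomputed)
  inconsistent <- !is.na(pct) & abs(pct - recomputed) > 0.5
  if (any(inconsistent)) {
    abort(glue::glue(
      "percent_reported inconsistent with counts for sponsor(s): ",
      "{paste(out$sponsor_name[inconsistent], collapse = ', ')}"
    ))
  }
  dplyr::arrange(out, pd_as_date(.data$snapshot_date), .data$sponsor_name)
}

#' Pick the tracker sponsor representing an institution
#'
#' When more than one tracker sponsor name maps to the same institution, the
#' one with the most registered trials represents it; ties break
#' lexicographically (and are logged).
#'
#' @param candidates Tibble with columns `sponsor_name`, `trial_count`.
#' @return The selected sponsor name (length-1 character).
#' @export
select_sponsor_for_umc <- function(candidates) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0) {
    abort("no sponsor candidates supplied")
  }
  check_columns(candidates, c("sponsor_name", "trial_count"), "sponsor candidates")
  best <- candidates |>
    dplyr::filter(.data$trial_count == max(.data$trial_count)) |>
    dplyr::arrange(.data$sponsor_name)
  if (nrow(best) > 1) {
    inform(glue::glue(
      "sponsor tie at {best$trial_count[1]} trials; ",
      "keeping {best$sponsor_name[1]} by name order"
    ))
  }
  best$sponsor_name[[1]]
}
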