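#' Configuration for the synthetic trial cohort
#'
#' The generator is truth-first: it samples every behavior flag (was the
#' trial registered prospectively, does its abstract carry the TRN, ...)
#' and then renders registry records, publication texts and open-access
#' evidence that realize those flags exactly. Because every classifier in
#' the pipeline is deterministic, pipeline tallies on a synthetic cohort
#' must equal the sampled truth exactly — the basis of the end-to-end
#' tests. Default rates approximate the pooled rates observed across German
#' university medical centers, so a default cohort is also a realistic
#' demo.
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param n_umcs Number of institutions.
#' @param trials_per_umc Trials per institution.
#' @param registry_mix Fraction of trials registered in ClinicalTrials.gov
#'   (the rest in DRKS).
#' @param rates Named list of Bernoulli probabilities; see Details.
#' @param oa_mix Named distribution over open-access statuses
#'   (gold/hybrid/green/bronze/closed), summing to 1.
#' @param completion_window Two-element year range for completion dates.
#' @param reporting_delay List with integer `months` and matching `prob`:
#'   the delay distribution from completion to a results report (either
#'   route).
#' @param ctx [followup_context()] used for the truth's timeliness flags.
#'
#' @details Rates: `prospective`, `has_start_date`, `has_publication`,
#'   `dissertation`, `has_pmid`, `has_abstract`, `has_full_text`,
#'   `has_doi`, `trn_in_abstract`, `trn_in_full_text`,
#'   `link_in_registry_ctgov`, `link_in_registry_drks`,
#'   `summary_results_ctgov`, `summary_results_drks`,
#'   `cross_registration`, `decoy_trn` (chance an abstract without the
#'   trial's own TRN mentions a different trial's — exercises precision),
#'   `oa_has_date`.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_umcs = 5L,
                             trials_per_umc = 20L,
                             registry_mix = 0.78,
                             rates = list(),
                             oa_mix = c(gold = 0.14, hybrid = 0.10, green = 0.20,
                                        bronze = 0.10, closed = 0.46),
                             completion_window = c(2009L, 2017L),
                             reporting_delay = list(
                               months = c(3L, 9L, 15L, 21L, 30L, 42L, 60L, 84L),
                               prob = c(0.10, 0.17, 0.18, 0.18, 0.12, 0.10, 0.08, 0.07)
                             ),
                             ctx = followup_context()) {
  default_rates <- list(
    prospective = 0.55,
    has_start_date = 0.97,
    has_publication = 0.65,
    dissertation = 0.03,
    has_pmid = 0.97,
    has_abstract = 0.98,
    has_full_text = 0.90,
    has_doi = 0.95,
    trn_in_abstract = 0.38,
    trn_in_full_text = 0.60,
    link_in_registry_ctgov = 0.58,
    link_in_registry_drks = 0.23,
    summary_results_ctgov = 0.08,
    summary_results_drks = 0.03,
    cross_registration = 0.02,
    decoy_trn = 0.10,
    oa_has_date = 0.97
  )
  unknown <- setdiff(names(rates), names(default_rates))
  if (length(unknown) > 0) {
    abort(glue::glue("unknown rate(s): {paste(unknown, collapse = ', ')}"))
  }
  default_rates[names(rates)] <- rates
  probs <- c(unlist(default_rates), registry_mix, oa_mix, reporting_delay$prob)
  if (any(probs < 0 | probs > 1)) {
    abort("all rates and probabilities must lie in [0, 1]")
  }
  if (!setequal(names(oa_mix), oa_levels()) ||
      abs(sum(oa_mix) - 1) > 1e-8) {
    abort("`oa_mix` must cover gold/hybrid/green/bronze/closed and sum to 1")
  }
  if (length(reporting_delay$months) != length(reporting_delay$prob) ||
      abs(sum(reporting_delay$prob) - 1) > 1e-8) {
    abort("`reporting_delay` months and prob must align and prob must sum to 1")
  }
  if (completion_window[1] > completion_window[2] ||
      completion_window[1] < 1990 || completion_window[2] > 2100) {
    abort("`completion_window` must be an ascending range of plausible years")
  }
  structure(
    list(
      seed = as.integer(seed), n_umcs = as.integer(n_umcs),
      trials_per_umc = as.integer(trials_per_umc),
      registry_mix = registry_mix, rates = default_rates, oa_mix = oa_mix,
      completion_window = as.integer(completion_window),
      reporting_delay = reporting_delay, ctx = ctx
    ),
    class = "synthetic_config"
  )
}

#' Configuration mirroring the pooled rates of the audited cohort
#'
#' Returns a [synthetic_config()] sized like the real cohort (35
#' institutions, about 3,000 trials) whose behavior rates approximate the
#' pooled audit results: prospective registration about 55%, TRN in
#' abstract 38%, TRN in full text 60%, publication links in the registry
#' 58%/23% (ClinicalTrials.gov/DRKS), summary results 8%/3%, and about 54%
#' of publications openly accessible. The reporting-delay distribution puts
#' 63% of reports within 24 months, which makes timely reporting within 2
#' years come out near the observed 41% once publication and
#' summary-results prevalence are accounted for.
#'
#' @param seed Integer RNG seed.
#' @param trials_per_umc Trials per institution (86 gives ~3,000 trials).
#' @return A `synthetic_config`.
#' @export
paper_shaped_config <- function(seed = 1L, trials_per_umc = 86L) {
  synthetic_config(seed = seed, n_umcs = 35L, trials_per_umc = trials_per_umc)
}

#' Embed a registration number into a text template
#'
#' Replaces the `{trn}` placeholder with the identifier rendered in one of
#' the styles the detector must tolerate, and records the 0-based character
#' offset of the embedded number.
#'
#' @param template Text containing exactly one `{trn}` placeholder.
#' @param trn Canonical registration number.
#' @param style `"plain"`, `"spaced"` (space between prefix and digits) or
#'   `"lowercase"`.
#' @return Tibble with columns `text`, `char_offset`.
#' @export
embed_trn <- function(template, trn, style = c("plain", "spaced", "lowercase")) {
  style <- rlang::arg_match(style)
  pos <- regexpr("{trn}", template, fixed = TRUE)
  if (pos < 0) {
    abort("`template` must contain a single {trn} placeholder")
  }
  rendered <- switch(style,
    plain = trn,
    spaced = sub("^([A-Za-z]+)", "\\1 ", trn),
    lowercase = tolower(trn)
  )
  tibble(
    text = sub("{trn}", rendered, template, fixed = TRUE),
    char_offset = as.integer(pos - 1L)
  )
}

abstract_templates <- c(
  "Background: we conducted a randomized controlled study. The trial was registered ({trn}) before enrolment. Results are reported per protocol.",
  "This multicentre study (registration {trn}) evaluated the intervention against standard care in adult participants.",
  "Objective and methods are described for the registered study {trn}; outcomes were assessed at twelve months."
)

fulltext_template <- paste(
  "Introduction. Clinical context and rationale are described.",
  "Methods. The study protocol was approved by the local ethics committee",
  "and registered ({trn}). Participants were recruited at several sites.",
  "Results. Outcomes are reported for the full analysis set.",
  "Discussion. Findings are consistent with prior reports."
)

plain_templates <- function(templates) {
  vapply(templates, function(t) sub(" ?\\(?\\{trn\\}\\)?", "", t), character(1),
         USE.NAMES = FALSE)
}

sample_rate <- function(n, p) stats::runif(n) < p

month_seq_add <- function(date, n_months) {
  date %m+% months(as.integer(n_months))
}

#' Generate a seeded synthetic cohort with known truth
#'
#' Samples per-trial behavior flags under `config`, then renders registry
#' records (both dialects), publication metadata with abstract and full
#' texts, open-access location evidence, the trial-publication mapping and
#' synthetic EU-tracker history rows, together with a truth table holding
#' the value every transparency metric must take for every trial —
#' including `NA` where the trial falls outside a metric's denominator.
#' Cross-registered trials additionally emit a paired DRKS record whose
#' secondary-id link is placed on a randomly chosen side (or both), so
#' deduplication is exercised in both directions.
#'
#' @param config A [synthetic_config()].
#' @return List of class `ctdash_cohort` with elements `trials` (canonical
#'   tibble, both registries), `publications`, `links`, `oa` (location
#'   rows), `tracker`, `truth`, `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  r <- config$rates
  n <- config$n_umcs * config$trials_per_umc
  umc <- rep(sprintf("UMC_%02d", seq_len(config$n_umcs)),
             each = config$trials_per_umc)
  registry <- ifelse(sample_rate(n, config$registry_mix), "ctgov", "drks")
  trn <- ifelse(registry == "ctgov",
                sprintf("NCT%08d", 10000000L + seq_len(n)),
                sprintf("DRKS%08d", seq_len(n)))

  # latent calendar: completion inside the window, start before completion,
  # registration keyed to start by the prospective flag
  comp_year <- sample(seq(config$completion_window[1], config$completion_window[2]),
                      n, replace = TRUE)
  comp_month <- sample.int(12L, n, replace = TRUE)
  comp_day <- sample.int(28L, n, replace = TRUE) # ctgov day-resolved only
  comp_imputed <- as.Date(sprintf("%04d-%02d-01", comp_year, comp_month))
  comp_date_full <- as.Date(sprintf("%04d-%02d-%02d", comp_year, comp_month, comp_day))
  duration <- sample(6:48, n, replace = TRUE)
  start_month_date <- month_seq_add(comp_imputed, -duration)
  prospective <- sample_rate(n, r$prospective)
  reg_offset <- ifelse(prospective,
                       -sample(0:3, n, replace = TRUE),
                       sample(1:6, n, replace = TRUE))
  reg_month_date <- month_seq_add(start_month_date, reg_offset)
  has_start <- sample_rate(n, r$has_start_date)

  summary_rate <- ifelse(registry == "ctgov", r$summary_results_ctgov,
                         r$summary_results_drks)
  has_summary <- sample_rate(n, summary_rate)
  delay <- config$reporting_delay
  summary_delay <- sample(delay$months, n, replace = TRUE, prob = delay$prob)
  summary_date <- month_seq_add(comp_imputed, summary_delay)

  has_pub <- sample_rate(n, r$has_publication)
  dissertation <- has_pub & sample_rate(n, r$dissertation)
  pub_delay <- sample(delay$months, n, replace = TRUE, prob = delay$prob)
  pub_day_jitter <- sample(0:27, n, replace = TRUE)
  pub_date <- month_seq_add(comp_imputed, pub_delay) + pub_day_jitter
  has_pmid <- has_pub & sample_rate(n, r$has_pmid)
  has_abstract <- has_pub & sample_rate(n, r$has_abstract)
  has_full_text <- has_pub & sample_rate(n, r$has_full_text)
  has_doi <- has_pub & sample_rate(n, r$has_doi)
  trn_in_abs <- has_pub & sample_rate(n, r$trn_in_abstract)
  trn_in_ft <- has_pub & sample_rate(n, r$trn_in_full_text)
  link_rate <- ifelse(registry == "ctgov", r$link_in_registry_ctgov,
                      r$link_in_registry_drks)
  linked <- has_pub & sample_rate(n, link_rate)
  decoy <- sample_rate(n, r$decoy_trn)

  cross <- registry == "ctgov" & sample_rate(n, r$cross_registration)
  partner_trn <- ifelse(cross, sprintf("DRKS%08d", 90000000L + seq_len(n)), NA)
  cross_side <- sample(c("ctgov", "drks", "both"), n, replace = TRUE)

  oa_status <- sample(oa_levels(), n, replace = TRUE,
                      prob = config$oa_mix[oa_levels()])
  oa_dated <- has_pub & sample_rate(n, r$oa_has_date)
  style <- sample(c("plain", "spaced", "lowercase"), n, replace = TRUE)
  abs_template <- sample(abstract_templates, n, replace = TRUE)

  # --- render registry records -------------------------------------------
  pub_id <- ifelse(has_pub, paste0("pub-", tolower(trn)), NA)
  doi <- ifelse(has_doi, paste0("10.5555/", tolower(trn)), NA)
  pmid <- ifelse(has_pmid, sprintf("3%07d", seq_len(n)), NA)

  references <- purrr::map(seq_len(n), function(i) {
    refs <- tibble(title = "Study protocol", doi = NA_character_,
                   pmid = NA_character_, is_results_reference = FALSE)
    if (linked[i] && (has_doi[i] || has_pmid[i])) {
      refs <- dplyr::bind_rows(refs, tibble(
        title = "Results article",
        doi = if (has_doi[i]) doi[i] else NA_character_,
        pmid = if (has_pmid[i]) pmid[i] else NA_character_,
        is_results_reference = TRUE
      ))
    }
    if (registry[i] == "drks" && has_summary[i]) {
      refs <- dplyr::bind_rows(refs, tibble(
        title = "Ergebnisbericht (PDF)", doi = NA_character_,
        pmid = NA_character_, is_results_reference = FALSE
      ))
    }
    refs
  })

  month_gran <- registry == "drks"
  fmt_md <- function(d) format(d, "%Y-%m")
  trials <- tibble(
    trn = trn,
    registry = registry,
    lead_umcs = purrr::map(umc, identity),
    start_date = parse_partial_date(ifelse(
      has_start,
      ifelse(month_gran, fmt_md(start_month_date),
             format(start_month_date + (comp_day - 1) %% 28, "%Y-%m-%d")),
      NA
    )),
    completion_date = parse_partial_date(ifelse(
      month_gran, fmt_md(comp_imputed), format(comp_date_full, "%Y-%m-%d")
    )),
    registration_date = parse_partial_date(ifelse(
      month_gran, fmt_md(reg_month_date), format(reg_month_date, "%Y-%m-%d")
    )),
    status = "Completed",
    study_type = "interventional",
    has_structured_summary_results = registry == "ctgov" & has_summary,
    summary_results_date = parse_partial_date(ifelse(
      has_summary, format(summary_date, "%Y-%m-%d"), NA
    )),
    references = references,
    secondary_ids = purrr::map(seq_len(n), function(i) {
      if (cross[i] && cross_side[i] %in% c("ctgov", "both")) partner_trn[i] else character()
    }),
    cross_registrations = purrr::map(seq_len(n), ~ character())
  )

  partners <- if (any(cross)) {
    idx <- which(cross)
    main_trn <- trn # tibble() columns shadow outer names during construction
    tibble(
      trn = partner_trn[idx],
      registry = "drks",
      lead_umcs = purrr::map(umc[idx], identity),
      start_date = parse_partial_date(ifelse(has_start[idx],
                                             fmt_md(start_month_date[idx]), NA)),
      completion_date = parse_partial_date(fmt_md(comp_imputed[idx])),
      registration_date = parse_partial_date(fmt_md(reg_month_date[idx])),
      status = "Completed",
      study_type = "interventional",
      has_structured_summary_results = FALSE,
      summary_results_date = pd_na(length(idx)),
      references = purrr::map(idx, ~ tibble(
        title = "Studienprotokoll", doi = NA_character_, pmid = NA_character_,
        is_results_reference = FALSE
      )),
      secondary_ids = purrr::map(idx, function(i) {
        if (cross_side[i] %in% c("drks", "both")) main_trn[i] else character()
      }),
      cross_registrations = purrr::map(idx, ~ character())
    )
  } else {
    NULL
  }
  trials <- dplyr::bind_rows(trials, partners)

  # --- render publications ------------------------------------------------
  embed_or_not <- function(i, template, embed, own_pool) {
    if (embed) {
      # cross-registered trials sometimes carry the partner id instead,
      # which must still count as the trial's own
      id <- if (cross[i] && stats::runif(1) < 0.5) partner_trn[i] else trn[i]
      embed_trn(template, id, style[i])$text
    } else if (decoy[i]) {
      other <- trn[if (i == 1L) n else i - 1L]
      embed_trn(template, other, "plain")$text
    } else {
      sub(" ?\\(?\\{trn\\}\\)?", "", template)
    }
  }
  pubs_idx <- which(has_pub)
  publications <- tibble(
    pub_id = pub_id[pubs_idx],
    doi = doi[pubs_idx],
    pmid = pmid[pubs_idx],
    publication_date = parse_partial_date(format(pub_date[pubs_idx], "%Y-%m-%d")),
    is_dissertation = dissertation[pubs_idx],
    abstract_text = vapply(pubs_idx, function(i) {
      if (!has_abstract[i]) return(NA_character_)
      embed_or_not(i, abs_template[i], trn_in_abs[i])
    }, character(1)),
    full_text = vapply(pubs_idx, function(i) {
      if (!has_full_text[i]) return(NA_character_)
      embed_or_not(i, fulltext_template, trn_in_ft[i])
    }, character(1))
  )
  links <- tibble(trn = trn[pubs_idx], pub_id = pub_id[pubs_idx])

  # --- render open-access evidence ---------------------------------------
  oa_rows <- purrr::map_dfr(pubs_idx, function(i) {
    date <- if (oa_dated[i]) "2022-11-01" else NA_character_
    loc <- switch(oa_status[i],
      gold = tibble(host_type = "publisher", journal_is_oa = TRUE, license_open = TRUE),
      hybrid = tibble(host_type = "publisher", journal_is_oa = FALSE, license_open = TRUE),
      green = tibble(host_type = "repository", journal_is_oa = FALSE, license_open = TRUE),
      bronze = tibble(host_type = "publisher", journal_is_oa = FALSE, license_open = FALSE),
      closed = tibble(host_type = NA_character_, journal_is_oa = NA, license_open = NA)
    )
    if (oa_status[i] %in% c("gold", "hybrid") && stats::runif(1) < 0.3) {
      loc <- dplyr::bind_rows(loc, tibble(
        host_type = "repository", journal_is_oa = FALSE, license_open = TRUE
      ))
    }
    dplyr::mutate(loc, pub_id = pub_id[i], unpaywall_date = date, .before = 1)
  })

  # --- synthetic EU-tracker history --------------------------------------
  due_2020 <- sample(5:40, config$n_umcs, replace = TRUE)
  rep_2020 <- vapply(due_2020, function(d) sample.int(d + 1L, 1L) - 1L, integer(1))
  extra_due <- sample(0:10, config$n_umcs, replace = TRUE)
  due_2022 <- due_2020 + extra_due
  rep_2022 <- pmin(due_2022, rep_2020 + sample(0:15, config$n_umcs, replace = TRUE))
  tracker <- tibble(
    sponsor = rep(sprintf("UMC_%02d", seq_len(config$n_umcs)), times = 2),
    date = rep(c("2020-12-01", "2022-10-01"), each = config$n_umcs),
    total_due = c(due_2020, due_2022),
    total_reported = c(rep_2020, rep_2022)
  )

  # --- truth table --------------------------------------------------------
  dl <- pd_as_date(config$ctx$registry_download_date)
  search <- pd_as_date(config$ctx$publication_search_date)
  # reference completion date mirrors the rendered granularity: actual day
  # for ctgov records, first-of-month imputation for month-resolved drks
  comp_ref <- dplyr::if_else(registry == "ctgov", comp_date_full, comp_imputed)
  truth <- purrr::map_dfr(seq_len(n), function(i) {
    pub_ok <- has_pub[i] && !dissertation[i]
    abs_det <- pub_ok && has_pmid[i] && has_abstract[i]
    ft_det <- pub_ok && has_full_text[i]
    t_abs <- if (abs_det) trn_in_abs[i] else NA
    t_ft <- if (ft_det) trn_in_ft[i] else NA
    t_both <- if (abs_det && ft_det) trn_in_abs[i] && trn_in_ft[i] else NA
    t_link <- if (pub_ok && (has_doi[i] || has_pmid[i])) linked[i] else NA
    s_date <- if (has_summary[i]) summary_date[i] else as.Date(NA)
    p_date <- if (pub_ok) pub_date[i] else as.Date(NA)
    timely <- function(years, route) {
      deadline <- comp_ref[i] %m+% lubridate::years(years)
      elig <- switch(route,
        summary = deadline <= dl,
        publication = deadline <= search,
        either = deadline <= dl && deadline <= search
      )
      if (!elig) return(NA)
      rd <- switch(route,
        summary = s_date,
        publication = p_date,
        either = suppressWarnings(min(s_date, p_date, na.rm = TRUE))
      )
      !is.na(rd) && is.finite(rd) && rd <= deadline
    }
    oa_truth <- if (pub_ok && has_doi[i] && oa_dated[i]) oa_status[i] else NA_character_
    tibble(
      trn = trn[i], umc = umc[i], registry = registry[i],
      start_year = if (has_start[i]) as.integer(format(start_month_date[i], "%Y")) else NA_integer_,
      completion_year = comp_year[i],
      publication_year = if (pub_ok) as.integer(format(pub_date[i], "%Y")) else NA_integer_,
      prospective = if (has_start[i]) prospective[i] else NA,
      summary_results = has_summary[i],
      trn_in_abstract = t_abs, trn_in_full_text = t_ft, trn_in_both = t_both,
      link_in_registry = t_link,
      timely_2y_summary = timely(2, "summary"),
      timely_2y_publication = timely(2, "publication"),
      timely_2y_either = timely(2, "either"),
      timely_5y_summary = timely(5, "summary"),
      timely_5y_publication = timely(5, "publication"),
      timely_5y_either = timely(5, "either"),
      oa = factor(oa_truth, levels = oa_levels())
    )
  })

  structure(
    list(trials = trials, publications = publications, links = links,
         oa = oa_rows, tracker = tracker, truth = truth, config = config),
    class = "ctdash_cohort"
  )
}

#' Write a synthetic cohort to disk in the pipeline's input dialects
#'
#' Emits `trials_ctgov.csv`, `trials_drks.csv` (dialect column names),
#' `publications.csv`, `links.csv`, `oa.csv`, `tracker.csv` and
#' `truth.csv`.
#'
#' @param cohort A `ctdash_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ctdash_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dialects <- registry_dialects()
  fmt_pd <- function(x) format(x)
  for (reg in c("ctgov", "drks")) {
    sub <- dplyr::filter(cohort$trials, .data$registry == reg)
    map <- dialects[[reg]]
    flat <- tibble(
      !!map[["trn"]] := sub$trn,
      !!map[["lead_umcs"]] := purrr::map_chr(sub$lead_umcs, paste, collapse = ";"),
      !!map[["start_date"]] := fmt_pd(sub$start_date),
      !!map[["completion_date"]] := fmt_pd(sub$completion_date),
      !!map[["registration_date"]] := fmt_pd(sub$registration_date),
      !!map[["status"]] := sub$status,
      !!map[["study_type"]] := sub$study_type,
      !!map[["has_structured_summary_results"]] := tolower(as.character(sub$has_structured_summary_results)),
      !!map[["summary_results_date"]] := fmt_pd(sub$summary_results_date),
      !!map[["references"]] := purrr::map_chr(sub$references, function(r) {
        as.character(jsonlite::toJSON(r, na = "null"))
      }),
      !!map[["secondary_ids"]] := purrr::map_chr(sub$secondary_ids, paste, collapse = ";")
    )
    readr::write_csv(flat, file.path(dir, paste0("trials_", reg, ".csv")), na = "")
  }
  readr::write_csv(
    dplyr::mutate(cohort$publications,
                  publication_date = fmt_pd(.data$publication_date),
                  is_dissertation = tolower(as.character(.data$is_dissertation))),
    file.path(dir, "publications.csv"), na = ""
  )
  readr::write_csv(cohort$links, file.path(dir, "links.csv"), na = "")
  readr::write_csv(
    dplyr::mutate(cohort$oa,
                  journal_is_oa = tolower(as.character(.data$journal_is_oa)),
                  license_open = tolower(as.character(.data$license_open))),
    file.path(dir, "oa.csv"), na = ""
  )
  readr::write_csv(cohort$tracker, file.path(dir, "tracker.csv"), na = "")
  truth_flat <- dplyr::mutate(cohort$truth, oa = as.character(.data$oa))
  readr::write_csv(truth_flat, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}

#' @importFrom rlang := !!
NULL
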