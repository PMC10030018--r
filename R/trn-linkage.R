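#' Registration-number pattern inventory
#'
#' The regular expressions used to find trial registration numbers (TRNs) in
#' publication text, built from the registries' documented identifier
#' formats: `NCT` + 8 digits (ClinicalTrials.gov), `DRKS` + 8 digits,
#' `ISRCTN` + 8 digits, and the EudraCT `YYYY-NNNNNN-CC` number. Matching is
#' case-insensitive and tolerates one optional space or hyphen between
#' prefix and digits; digit-boundary guards reject ids embedded in longer
#' digit runs. Extend by binding extra rows (registry_key, pattern) before
#' passing to [detect_trns()].
#'
#' @return Tibble with columns `registry_key`, `pattern` (PCRE-style).
#' @export
trn_patterns <- function() {
  prefixed <- function(prefix, ndigits) {
    paste0("(?<![A-Za-z])", prefix, "[ -]?(?<!\\d)\\d{", ndigits, "}(?!\\d)")
  }
  tibble(
    registry_key = c("ctgov", "drks", "isrctn", "eudract"),
    pattern = c(
      prefixed("NCT", 8),
      prefixed("DRKS", 8),
      prefixed("ISRCTN", 8),
      "(?<![\\d-])\\d{4}-\\d{6}-\\d{2}(?![\\d-])"
    )
  )
}

canonicalize_trn_hit <- function(raw, registry_key) {
  if (registry_key == "eudract") {
    return(raw)
  }
  toupper(stringr::str_remove_all(raw, "[ -]"))
}

#' Detect trial registration numbers in free text
#'
#' Scans a single text for every pattern in the inventory and returns one
#' hit per distinct canonical id per registry, keeping the 0-based character
#' offset of its first occurrence. Canonicalization uppercases and removes
#' the optional space/hyphen between prefix and digits (EudraCT numbers keep
#' their internal hyphens); canonical ids re-scan to themselves.
#'
#' @param text A length-1 character string (may be empty or `NA`).
#' @param patterns Pattern inventory, see [trn_patterns()].
#' @param source Optional label (`"abstract"`, `"full_text"`,
#'   `"registration"`) recorded on each hit.
#' @return Tibble with columns `registry_key`, `canonical_id`, `char_offset`,
#'   `source`.
#' @examples
#' detect_trns("Registered at NCT01234567 and drks 00004871.")
#' @export
detect_trns <- function(text, patterns = trn_patterns(), source = NA_character_) {
  stopifnot(length(text) == 1)
  empty <- tibble(
    registry_key = character(), canonical_id = character(),
    char_offset = integer(), source = character()
  )
  if (is.na(text) || !nzchar(text)) {
    return(empty)
  }
  hits <- purrr::pmap(patterns, function(registry_key, pattern) {
    loc <- stringr::str_locate_all(text, stringr::regex(pattern, ignore_case = TRUE))[[1]]
    if (nrow(loc) == 0) {
      return(NULL)
    }
    raw <- stringr::str_sub(text, loc[, "start"], loc[, "end"])
    tibble(
      registry_key = registry_key,
      canonical_id = canonicalize_trn_hit(raw, registry_key),
      char_offset = as.integer(loc[, "start"] - 1L),
      source = source
    )
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(empty)
  }
  out |>
    dplyr::arrange(.data$char_offset) |>
    dplyr::distinct(.data$registry_key, .data$canonical_id, .keep_all = TRUE)
}

#' Normalize a DOI to canonical form
#'
#' Strips resolver prefixes (`https://doi.org/`, `http://dx.doi.org/`,
#' `doi:`), trims whitespace and trailing punctuation, and lowercases (DOIs
#' are case-insensitive). Anything that does not then start with `10.` is
#' rejected.
#'
#' @param x Character vector of DOI strings.
#' @return Canonical lowercase DOIs.
#' @examples
#' normalize_doi("https://doi.org/10.1371/JOURNAL.PMED.1004175")
#' @export
normalize_doi <- function(x) {
  out <- trimws(as.character(x))
  out <- stringr::str_remove(out, stringr::regex(
    "^(https?://(dx\\.)?doi\\.org/|doi:\\s*)", ignore_case = TRUE
  ))
  out <- stringr::str_remove(out, "[.,;)\\]]+$")
  out <- tolower(out)
  bad <- !is.na(out) & !startsWith(out, "10.")
  if (any(bad)) {
    abort(glue::glue(
      "not a DOI: {paste(sQuote(unique(x[bad])), collapse = ', ')}"
    ))
  }
  out
}

#' Read publication metadata
#'
#' @param path CSV or JSON-lines file with columns `pub_id`, `doi`, `pmid`,
#'   `publication_date`, `is_dissertation`, `abstract_text` and either
#'   `full_text` (inline) or `full_text_path` (plain-text file, resolved
#'   relative to the input file).
#' @return Tibble of publications with `publication_date` parsed to
#'   [partial_date()] and full text loaded into `full_text`.
#' @export
read_publications <- function(path) {
  raw <- read_records(path)
  check_columns(raw, c("pub_id", "publication_date"), "publication file")
  get <- function(col, default = NA_character_) {
    if (col %in% names(raw)) as.character(raw[[col]]) else rep(default, nrow(raw))
  }
  full_text <- get("full_text")
  ft_path <- get("full_text_path")
  needs_file <- is.na(full_text) & !is.na(ft_path) & nzchar(ft_path)
  if (any(needs_file)) {
    base <- dirname(path)
    full_text[needs_file] <- vapply(ft_path[needs_file], function(p) {
      fp <- if (file.exists(p)) p else file.path(base, p)
      if (!file.exists(fp)) {
        abort(glue::glue("full text file not found: {p}"))
      }
      readr::read_file(fp)
    }, character(1))
  }
  doi <- get("doi")
  doi[!is.na(doi)] <- normalize_doi(doi[!is.na(doi)])
  tibble(
    pub_id = get("pub_id"),
    doi = doi,
    pmid = get("pmid"),
    publication_date = parse_partial_date(raw$publication_date),
    is_dissertation = as_flag(get("is_dissertation", "false")),
    abstract_text = get("abstract_text"),
    full_text = full_text
  )
}

#' Read the trial-publication mapping
#'
#' Two-column file (`trn`, `pub_id`) naming the earliest identified results
#' publication per trial (produced upstream by the manual multi-engine
#' search, which this pipeline consumes rather than re-runs).
#'
#' @param path CSV file.
#' @return Tibble with canonicalized `trn` and `pub_id`.
#' @export
read_trial_publication_links <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, c("trn", "pub_id"), "trial-publication mapping")
  tibble(trn = normalize_trn(raw$trn), pub_id = raw$pub_id)
}

trial_own_ids <- function(trial_trn, cross_registrations) {
  normalize_trn(c(trial_trn, cross_registrations))
}

text_contains_trn <- function(text, own_ids, patterns) {
  hits <- detect_trns(text, patterns)
  any(normalize_trn(hits$canonical_id) %in% own_ids)
}

#' Assess registry-publication linkage for trial-publication pairs
#'
#' For each (trial, earliest results publication) pair, computes the three
#' bidirectional-link flags with their denominator rules:
#'
#' * `trn_in_abstract` — `NA` unless the publication has a PubMed identifier
#'   and an abstract; else whether the trial's TRN (or a known
#'   cross-registration's TRN) is detected in the abstract.
#' * `trn_in_full_text` — `NA` unless a full text was retrieved; else
#'   whether the TRN occurs anywhere in it.
#' * `publication_linked_in_registry` — `NA` unless the publication has a
#'   DOI or PMID; else whether any registry reference carries the same
#'   normalized DOI or PMID.
#'
#' Dissertations carry metadata but are excluded from all publication-based
#' metrics, so every flag is `NA` for them. Flags are `NA` (absent), never
#' `FALSE`, exactly when the metric's sample condition fails.
#'
#' @param trials Canonical trial tibble (after deduplication).
#' @param publications Tibble from [read_publications()].
#' @param links Mapping from [read_trial_publication_links()].
#' @param patterns TRN pattern inventory.
#' @return Tibble with one row per trial: `trn`, `pub_id` (`NA` when the
#'   trial has no identified publication), `trn_in_abstract`,
#'   `trn_in_full_text`, `trn_in_both`, `publication_linked_in_registry`.
#' @export
assess_trn_links <- function(trials, publications, links,
                             patterns = trn_patterns()) {
  unknown_trn <- setdiff(links$trn, trials$trn)
  if (length(unknown_trn) > 0) {
    abort(glue::glue(
      "link mapping references unknown trial(s): ",
      "{paste(unknown_trn, collapse = ', ')}"
    ))
  }
  unknown_pub <- setdiff(links$pub_id, publications$pub_id)
  if (length(unknown_pub) > 0) {
    abort(glue::glue(
      "link mapping references unknown publication(s): ",
      "{paste(unknown_pub, collapse = ', ')}"
    ))
  }
  pub_by_id <- split(publications, publications$pub_id)
  link_by_trn <- stats::setNames(links$pub_id, links$trn)
  purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    trial <- trials[i, ]
    pub_id <- unname(link_by_trn[trial$trn])
    base <- tibble(
      trn = trial$trn, pub_id = pub_id %||% NA_character_,
      trn_in_abstract = NA, trn_in_full_text = NA, trn_in_both = NA,
      publication_linked_in_registry = NA
    )
    if (is.na(base$pub_id)) {
      return(base)
    }
    pub <- pub_by_id[[base$pub_id]][1, ]
    if (isTRUE(pub$is_dissertation)) {
      return(base)
    }
    own <- trial_own_ids(trial$trn, trial$cross_registrations[[1]])
    if (!is.na(pub$pmid) && !is.na(pub$abstract_text) && nzchar(pub$abstract_text)) {
      base$trn_in_abstract <- text_contains_trn(pub$abstract_text, own, patterns)
    }
    if (!is.na(pub$full_text) && nzchar(pub$full_text)) {
      base$trn_in_full_text <- text_contains_trn(pub$full_text, own, patterns)
    }
    # "both" is only determined when both constituent metrics are; plain `&`
    # would turn FALSE & NA into FALSE and leak out-of-sample trials in
    base$trn_in_both <- if (is.na(base$trn_in_abstract) || is.na(base$trn_in_full_text)) {
      NA
    } else {
      base$trn_in_abstract && base$trn_in_full_text
    }
    if (!is.na(pub$doi) || !is.na(pub$pmid)) {
      refs <- trial$references[[1]]
      ref_dois <- refs$doi[!is.na(refs$doi)]
      ref_dois <- tryCatch(normalize_doi(ref_dois), error = function(e) character())
      doi_match <- !is.na(pub$doi) && normalize_doi(pub$doi) %in% ref_dois
      pmid_match <- !is.na(pub$pmid) && pub$pmid %in% refs$pmid[!is.na(refs$pmid)]
      base$publication_linked_in_registry <- doi_match || pmid_match
    }
    base
  })
}
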