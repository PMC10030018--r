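# minimal canonical trial rows for unit fixtures; defaults pass every filter
make_trial <- function(trn = "NCT10000001",
                       registry = "ctgov",
                       umc = "UMC_01",
                       start = "2014-01-15",
                       completion = "2015-06-15",
                       registration = "2013-12-01",
                       status = "Completed",
                       study_type = "interventional",
                       structured_summary = FALSE,
                       summary_date = NA,
                       references = NULL,
                       secondary_ids = character(),
                       cross_registrations = character()) {
  tibble::tibble(
    trn = trn,
    registry = registry,
    lead_umcs = list(umc),
    start_date = parse_partial_date(start),
    completion_date = parse_partial_date(completion),
    registration_date = parse_partial_date(registration),
    status = status,
    study_type = study_type,
    has_structured_summary_results = structured_summary,
    summary_results_date = parse_partial_date(summary_date),
    references = list(references %||% tibble::tibble(
      title = character(), doi = character(), pmid = character(),
      is_results_reference = logical()
    )),
    secondary_ids = list(secondary_ids),
    cross_registrations = list(cross_registrations)
  )
}

make_publication <- function(pub_id = "pub-1",
                             doi = "10.5555/example",
                             pmid = "30000001",
                             date = "2016-03-10",
                             dissertation = FALSE,
                             abstract = "Registered trial.",
                             full_text = "Methods and results.") {
  tibble::tibble(
    pub_id = pub_id, doi = doi, pmid = pmid,
    publication_date = parse_partial_date(date),
    is_dissertation = dissertation,
    abstract_text = abstract, full_text = full_text
  )
}

ref_row <- function(title = "Results article", doi = NA_character_,
                    pmid = NA_character_, results = TRUE) {
  tibble::tibble(title = title, doi = doi, pmid = pmid,
                 is_results_reference = results)
}

`%||%` <- rlang::`%||%`
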