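test_that("cohort filters apply in order and conserve counts", {
  trials <- dplyr::bind_rows(
    purrr::map(1:7, ~ make_trial(trn = sprintf("NCT1000000%d", .x))),
    make_trial(trn = "NCT20000001", completion = "2008-06-01"),
    make_trial(trn = "NCT20000002", completion = "2008-06-01",
               study_type = "observational"), # completion wins: first reason
    make_trial(trn = "NCT20000003", study_type = "observational")
  )
  kept <- apply_cohort_filters(trials, cohort_criteria())
  tally <- exclusion_tally(kept)
  expect_equal(nrow(kept), 7)
  counts <- setNames(tally$excluded_by_reason$n, tally$excluded_by_reason$reason)
  expect_equal(unname(counts["completion_date_outside_window"]), 2L)
  expect_equal(unname(counts["status_not_complete"]), 0L)
  expect_equal(unname(counts["not_interventional"]), 1L)
  expect_equal(tally$input_count,
               tally$included_count + tally$duplicates_removed + sum(counts))
})

test_that("filters are idempotent and handle empty input", {
  empty <- apply_cohort_filters(make_trial()[0, ], cohort_criteria())
  expect_equal(nrow(empty), 0)
  expect_equal(exclusion_tally(empty)$input_count, 0L)

  trials <- dplyr::bind_rows(purrr::map(1:5, ~ make_trial(
    trn = sprintf("NCT1000000%d", .x)
  )))
  once <- apply_cohort_filters(trials, cohort_criteria())
  twice <- apply_cohort_filters(once, cohort_criteria())
  expect_equal(nrow(twice), nrow(once))
  expect_equal(sum(exclusion_tally(twice)$excluded_by_reason$n), 0L)
})

test_that("conservation holds on randomized fixtures", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:25, 1)
    trials <- dplyr::bind_rows(purrr::map(seq_len(n), function(i) {
      make_trial(
        trn = sprintf("NCT%08d", i),
        completion = sprintf("%d-05-01", sample(2006:2020, 1)),
        status = sample(c("Completed", "Recruiting", "Terminated"), 1),
        study_type = sample(c("interventional", "observational"), 1)
      )
    }))
    kept <- apply_cohort_filters(trials, cohort_criteria())
    tally <- exclusion_tally(kept)
    expect_equal(
      tally$input_count,
      tally$included_count + tally$duplicates_removed +
        sum(tally$excluded_by_reason$n)
    )
  }
})

test_that("missing completion dates are excluded under the window reason", {
  trials <- dplyr::bind_rows(
    make_trial(),
    make_trial(trn = "NCT10000002", completion = NA)
  )
  expect_message(
    kept <- apply_cohort_filters(trials, cohort_criteria()),
    "missing completion date"
  )
  expect_equal(nrow(kept), 1)
  tally <- exclusion_tally(kept)
  expect_equal(tally$excluded_by_reason$n[1], 1L)
})

test_that("cross-registrations collapse to the ctgov member from either side", {
  drks_refs <- ref_row(title = "Ergebnisbericht", results = FALSE)
  pair_ctgov_side <- dplyr::bind_rows(
    make_trial(trn = "NCT10000001", secondary_ids = "DRKS00004871"),
    make_trial(trn = "DRKS00004871", registry = "drks", references = drks_refs)
  )
  pair_drks_side <- dplyr::bind_rows(
    make_trial(trn = "NCT10000001"),
    make_trial(trn = "DRKS00004871", registry = "drks",
               references = drks_refs, secondary_ids = "NCT10000001")
  )
  for (trials in list(pair_ctgov_side, pair_drks_side)) {
    out <- deduplicate_cross_registrations(trials)
    expect_equal(nrow(out), 1)
    expect_equal(out$registry, "ctgov")
    expect_equal(out$cross_registrations[[1]], "DRKS00004871")
    # union of references merged onto the retained member
    expect_true("Ergebnisbericht" %in% out$references[[1]]$title)
    log <- dedup_log(out)
    expect_equal(log$trn_kept, "NCT10000001")
    expect_equal(log$trn_removed, "DRKS00004871")
  }
})

test_that("normalization bridges spacing and case in secondary ids", {
  trials <- dplyr::bind_rows(
    make_trial(trn = "NCT10000001", secondary_ids = "drks 0000-4871"),
    make_trial(trn = "DRKS00004871", registry = "drks")
  )
  out <- deduplicate_cross_registrations(trials)
  expect_equal(nrow(out), 1)
})

test_that("unrelated trials and empty input pass through dedup unchanged", {
  trials <- dplyr::bind_rows(
    make_trial(trn = "NCT10000001"),
    make_trial(trn = "DRKS00009999", registry = "drks")
  )
  out <- deduplicate_cross_registrations(trials)
  expect_equal(nrow(out), 2)
  expect_equal(nrow(dedup_log(out)), 0)
})

test_that("tracker history recomputes percentages and validates counts", {
  rows <- tibble::tibble(
    sponsor = c("A", "A"),
    date = c("2022-10-04", "2020-12-01"),
    total_due = c(813L, 541L),
    total_reported = c(647L, 223L)
  )
  out <- read_euctr_tracker_history(rows)
  # sorted by snapshot date
  expect_equal(out$total_due, c(541L, 813L))
  expect_equal(round(out$percent_reported, 1), c(41.2, 79.6))
  bad <- tibble::tibble(sponsor = "B", date = "2021-01-01",
                        total_due = 10L, total_reported = 12L)
  expect_error(read_euctr_tracker_history(bad), "B")
})

test_that("sponsor selection picks the largest and breaks ties by name", {
  expect_equal(select_sponsor_for_umc(
    tibble::tibble(sponsor_name = c("X", "Y"), trial_count = c(14L, 3L))
  ), "X")
  expect_equal(select_sponsor_for_umc(
    tibble::tibble(sponsor_name = "X", trial_count = 5L)
  ), "X")
  expect_message(
    pick <- select_sponsor_for_umc(
      tibble::tibble(sponsor_name = c("B", "A"), trial_count = c(4L, 4L))
    ),
    "tie"
  )
  expect_equal(pick, "A")
  expect_error(select_sponsor_for_umc(tibble::tibble()), "candidates")
})

test_that("trial readers round-trip the generator's dialect files", {
  cohort <- generate_cohort(synthetic_config(seed = 11, n_umcs = 2,
                                             trials_per_umc = 8))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  ctgov <- read_trials(file.path(dir, "trials_ctgov.csv"), "ctgov")
  drks <- read_trials(file.path(dir, "trials_drks.csv"), "drks")
  back <- dplyr::bind_rows(ctgov, drks)
  expect_setequal(back$trn, cohort$trials$trn)
  orig <- cohort$trials[match(back$trn, cohort$trials$trn), ]
  expect_equal(format(back$completion_date), format(orig$completion_date))
  expect_equal(back$has_structured_summary_results,
               orig$has_structured_summary_results)
  expect_equal(purrr::map_int(back$references, nrow),
               purrr::map_int(orig$references, nrow))
})

test_that("readers accept JSON-lines records", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "trials.jsonl")
  rec <- list(
    nct_id = "NCT10000001", lead_umcs = "UMC_01",
    start_date = "2014-01-15", completion_date = "2015-06-15",
    study_first_submitted_date = "2013-12-01",
    overall_status = "Completed", study_type = "interventional",
    has_summary_results = "true",
    references = list(list(title = "Results article", doi = "10.1/abc",
                           pmid = "123", is_results_reference = TRUE)),
    secondary_ids = list("DRKS00000001")
  )
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), path)
  out <- read_trials(path, "ctgov")
  expect_equal(out$trn, "NCT10000001")
  expect_true(out$has_structured_summary_results)
  expect_equal(out$references[[1]]$doi, "10.1/abc")
  expect_equal(out$secondary_ids[[1]], "DRKS00000001")
})

test_that("missing required columns are named in the error", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  readr::write_csv(tibble::tibble(nct_id = "NCT10000001"), path)
  expect_error(read_trials(path, "ctgov"), "completion_date")
})
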