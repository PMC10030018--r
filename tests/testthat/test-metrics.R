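test_that("prospective registration follows the month-granular rule", {
  reg <- parse_partial_date(c("2015-03", "2015-04", "2015-02", "2015"))
  start <- parse_partial_date(c("2015-03", "2015-03", "2015-03", "2015-03"))
  expect_equal(is_prospectively_registered(reg, start),
               c(TRUE, FALSE, TRUE, NA))
  # missing start month -> not assessable
  expect_true(is.na(is_prospectively_registered(
    parse_partial_date("2015-03"), parse_partial_date("2015")
  )))
})

test_that("summary results use the structured field or DRKS keywords", {
  trials <- dplyr::bind_rows(
    make_trial(trn = "NCT10000001", structured_summary = TRUE),
    make_trial(trn = "NCT10000002", structured_summary = FALSE),
    make_trial(trn = "DRKS00000001", registry = "drks",
               references = ref_row(title = "Ergebnisbericht (PDF)",
                                    results = FALSE)),
    make_trial(trn = "DRKS00000002", registry = "drks",
               references = ref_row(title = "Studienprotokoll",
                                    results = FALSE)),
    make_trial(trn = "DRKS00000003", registry = "drks",
               references = ref_row(title = "ABSCHLUSSBERICHT 2019",
                                    results = FALSE))
  )
  expect_equal(has_summary_results(trials), c(TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("route report dates take the earlier defined date", {
  s <- parse_partial_date("2018-01-05")
  p <- parse_partial_date("2017-06-20")
  none <- parse_partial_date(NA)
  expect_equal(format(route_report_date(s, p, "either")), "2017-06-20")
  expect_equal(format(route_report_date(s, p, "summary")), "2018-01-05")
  expect_true(is.na(route_report_date(none, none, "publication")))
  expect_equal(format(route_report_date(s, none, "either")), "2018-01-05")
})

test_that("follow-up eligibility uses the route's observation date", {
  ctx <- followup_context("2022-11-01", "2022-02-15")
  late <- parse_partial_date("2017-12")
  early <- parse_partial_date("2015-06")
  # 2017-12 + 5y = 2022-12-01 > download date
  expect_false(is_eligible_for_followup(late, "summary", 5, ctx))
  expect_true(is_eligible_for_followup(early, "summary", 5, ctx))
  # either route needs both windows closed; search date is earlier
  mid <- parse_partial_date("2020-06")
  expect_true(is_eligible_for_followup(mid, "summary", 2, ctx))
  expect_false(is_eligible_for_followup(mid, "publication", 2, ctx))
  expect_false(is_eligible_for_followup(mid, "either", 2, ctx))
  # year-only completion is not assessable
  expect_false(is_eligible_for_followup(parse_partial_date("2015"), "summary", 2, ctx))
})

test_that("timeliness flags combine eligibility and report dates", {
  ctx <- followup_context("2022-11-01", "2022-02-15")
  mk <- function(completion, pub_date) {
    trial <- make_trial(completion = completion)
    pub <- make_publication(date = pub_date)
    links <- tibble::tibble(trn = trial$trn, pub_id = pub$pub_id)
    assess_trials(trial, pub, links, ctx = ctx)
  }
  within <- mk("2015-06-15", "2017-05-01")
  expect_true(within$timely_2y_publication)
  beyond <- mk("2015-06-15", "2017-07-01")
  expect_false(beyond$timely_2y_publication)
  expect_true(beyond$timely_5y_publication)
  ineligible <- mk("2021-03-15", "2021-09-01")
  expect_true(is.na(ineligible$timely_2y_publication))
})

test_that("dissertation-only publications never feed publication metrics", {
  trial <- make_trial(completion = "2015-06-15")
  pub <- make_publication(date = "2016-01-10", dissertation = TRUE)
  links <- tibble::tibble(trn = trial$trn, pub_id = pub$pub_id)
  out <- assess_trials(trial, pub, links)
  expect_false(out$timely_2y_publication) # eligible but unreported
  expect_true(is.na(out$trn_in_abstract))
  expect_true(is.na(out$oa) || is.na(as.character(out$oa)))
  expect_true(is.na(out$publication_year))
})

test_that("open-access classification follows the descending hierarchy", {
  ev <- function(...) tibble::tribble(...)
  expect_equal(as.character(classify_oa_status(ev(
    ~host_type, ~journal_is_oa, ~license_open,
    "repository", FALSE, TRUE,
    "publisher", FALSE, TRUE
  ))), "hybrid")
  expect_equal(as.character(classify_oa_status(NULL)), "closed")
  expect_equal(as.character(classify_oa_status(ev(
    ~host_type, ~journal_is_oa, ~license_open,
    "publisher", FALSE, FALSE,
    "publisher", TRUE, FALSE
  ))), "gold")
  expect_equal(as.character(classify_oa_status(ev(
    ~host_type, ~journal_is_oa, ~license_open,
    "publisher", FALSE, FALSE
  ))), "bronze")
  expect_error(classify_oa_status(ev(
    ~host_type, ~journal_is_oa, ~license_open, "preprint", FALSE, FALSE
  )), "host_type")
})

test_that("open-access classification is permutation invariant", {
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(1:5, 1)
    evidence <- tibble::tibble(
      host_type = sample(c("publisher", "repository"), k, replace = TRUE),
      journal_is_oa = sample(c(TRUE, FALSE), k, replace = TRUE),
      license_open = sample(c(TRUE, FALSE), k, replace = TRUE)
    )
    ref <- classify_oa_status(evidence)
    for (p in 1:3) {
      perm <- evidence[sample.int(k), ]
      expect_equal(classify_oa_status(perm), ref)
    }
  }
})

test_that("the OA metric sample needs a DOI and a dated record", {
  pub <- make_publication()
  rec <- list(unpaywall_date = "2022-11-01",
              evidence = tibble::tibble(host_type = "repository",
                                        journal_is_oa = FALSE,
                                        license_open = TRUE))
  expect_equal(as.character(oa_metric_sample(pub, rec)), "green")
  expect_true(is.na(oa_metric_sample(dplyr::mutate(pub, doi = NA_character_), rec)))
  undated <- rec
  undated$unpaywall_date <- NA_character_
  expect_true(is.na(oa_metric_sample(pub, undated)))
  empty <- list(unpaywall_date = "2022-11-01",
                evidence = rec$evidence[0, ])
  expect_equal(as.character(oa_metric_sample(pub, empty)), "closed")
})

test_that("5-year reporting dominates 2-year reporting where both defined", {
  cohort <- generate_cohort(synthetic_config(seed = 5, n_umcs = 4,
                                             trials_per_umc = 30))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  res <- run_audit(
    trials = c(ctgov = file.path(dir, "trials_ctgov.csv"),
               drks = file.path(dir, "trials_drks.csv")),
    publications = file.path(dir, "publications.csv"),
    links = file.path(dir, "links.csv"),
    oa = file.path(dir, "oa.csv"),
    out_dir = file.path(dir, "out"), formats = "csv"
  )
  a <- res$assessments
  for (route in c("summary", "publication", "either")) {
    t2 <- a[[paste0("timely_2y_", route)]]
    t5 <- a[[paste0("timely_5y_", route)]]
    both <- !is.na(t2) & !is.na(t5)
    expect_true(all(!t2[both] | t5[both])) # t2 => t5
    if (sum(both) > 0) {
      expect_gte(mean(t5[both]), mean(t2[both]))
    }
  }
  # either-route dominance where eligible for both
  both_ok <- !is.na(a$timely_2y_either)
  covered <- (!is.na(a$timely_2y_summary) & a$timely_2y_summary) |
    (!is.na(a$timely_2y_publication) & a$timely_2y_publication)
  expect_true(all(a$timely_2y_either[both_ok & covered]))
})

test_that("precomputed open-access statuses are accepted verbatim", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "oa.csv")
  readr::write_csv(tibble::tibble(pub_id = "pub-1", oa_status = "hybrid"), path)
  oa_tbl <- read_oa_evidence(path, mode = "status")
  expect_equal(as.character(oa_tbl$oa_status), "hybrid")
  trial <- make_trial()
  pub <- make_publication()
  links <- tibble::tibble(trn = trial$trn, pub_id = pub$pub_id)
  out <- assess_trials(trial, pub, links, oa = oa_tbl)
  expect_equal(as.character(out$oa), "hybrid")
  readr::write_csv(tibble::tibble(pub_id = "p", oa_status = "purple"),
                   path)
  expect_error(read_oa_evidence(path, mode = "status"), "purple")
})
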