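small_audit <- function(seed = 17, formats = c("csv", "json", "html")) {
  cohort <- generate_cohort(synthetic_config(seed = seed, n_umcs = 2,
                                             trials_per_umc = 15))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_cohort(cohort, dir)
  res <- run_audit(
    trials = c(ctgov = file.path(dir, "trials_ctgov.csv"),
               drks = file.path(dir, "trials_drks.csv")),
    publications = file.path(dir, "publications.csv"),
    links = file.path(dir, "links.csv"),
    oa = file.path(dir, "oa.csv"),
    tracker = file.path(dir, "tracker.csv"),
    out_dir = file.path(dir, "out"),
    formats = formats
  )
  list(res = res, dir = dir)
}

test_that("the dataset bundles one page per institution plus the pooled view", {
  run <- small_audit()
  ds <- run$res$dashboard
  expect_equal(length(ds$umc_pages), 2)
  expect_setequal(names(ds$umc_pages), c("UMC_01", "UMC_02"))
  expect_true(all(ds$all_umc_page$group_type != "umc"))
  expect_true(length(ds$provenance) > 0)
  # conservation: per-institution numerators sum to the pooled numerator
  for (m in metric_ids()) {
    rows <- dplyr::filter(ds$metrics, metric == m)
    pooled <- dplyr::filter(rows, group_type == "all")
    per_umc <- dplyr::filter(rows, group_type == "umc")
    expect_equal(sum(per_umc$x), pooled$x)
    expect_equal(sum(per_umc$n), pooled$n)
  }
})

test_that("the dataset round-trips through JSON unchanged", {
  run <- small_audit(formats = "json")
  ds <- run$res$dashboard
  path <- file.path(run$dir, "out", "dashboard.json")
  back <- read_dashboard_json(path)
  expect_equal(
    tibble::as_tibble(back$metrics),
    tibble::as_tibble(ds$metrics)[names(back$metrics)]
  )
  expect_equal(back$euctr_series$total_due, ds$euctr_series$total_due)
})

test_that("rendering is deterministic and self-consistent across formats", {
  run <- small_audit()
  out1 <- file.path(run$dir, "out")
  files <- c("index.html", "compare.html", "umc-umc-01.html", "summaries.csv",
             "dashboard.json")
  expect_true(all(file.exists(file.path(out1, files))))

  out2 <- file.path(run$dir, "out2")
  render_static_site(run$res$dashboard, report_config(out2))
  for (f in files) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }

  # every percentage printed in the pooled page is backed by the CSV export
  csv <- readr::read_csv(file.path(out1, "summaries.csv"),
                         show_col_types = FALSE)
  html <- paste(readLines(file.path(out1, "index.html")), collapse = "")
  shown <- stringr::str_match_all(html, "(\\d+)% \\((\\d+)/(\\d+)\\)")[[1]]
  expect_gt(nrow(shown), 5)
  for (i in seq_len(nrow(shown))) {
    hit <- dplyr::filter(csv, percent == as.integer(shown[i, 2]),
                         x == as.integer(shown[i, 3]),
                         n == as.integer(shown[i, 4]))
    expect_gt(nrow(hit), 0, label = paste("html figure", shown[i, 1]))
  }
})

test_that("empty metrics render an explicit placeholder", {
  summaries <- tibble::tibble(
    metric = "prospective", group_type = "all", group = "all",
    x = 0L, n = 0L, p = NA_real_, lower = NA_real_, upper = NA_real_
  )
  class(summaries) <- c("ctdash_summary", class(summaries))
  expect_warning(ds <- build_dashboard_dataset(summaries), "gaps")
  dir <- withr::local_tempdir()
  render_static_site(ds, report_config(dir, "html"))
  html <- paste(readLines(file.path(dir, "index.html")), collapse = "")
  expect_match(html, "no data")
})

test_that("schema problems surface as named-column errors", {
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(nct_id = "NCT10000001"),
                   file.path(dir, "trials.csv"))
  expect_error(
    run_audit(trials = c(ctgov = file.path(dir, "trials.csv")),
              publications = "x", links = "y",
              out_dir = file.path(dir, "out")),
    "overall_status|completion_date"
  )
})

test_that("tidy and glance expose the audit the broom way", {
  run <- small_audit(formats = "csv")
  td <- tidy(run$res)
  expect_true(all(c("metric", "group", "p", "lower", "upper") %in% names(td)))
  gl <- glance(run$res)
  expect_equal(gl$n_trials, nrow(run$res$assessments))
  expect_equal(gl$duplicates_removed, run$res$tally$duplicates_removed)
  plot <- ggplot2::autoplot(run$res$summaries, metric = "prospective")
  expect_s3_class(plot, "ggplot")
  trend <- plot_metric_trend(run$res$summaries, "timely_2y_either")
  expect_s3_class(trend, "ggplot")
})

test_that("the command-line interface completes a simulate-audit-report round trip", {
  cli <- system.file("cli", "ctdash", package = "ctdash")
  skip_if(cli == "", "CLI script not found")
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  run_cli <- function(...) {
    suppressWarnings(system2(rscript, c(cli, ...), stdout = TRUE, stderr = TRUE,
                             env = libs))
  }
  md5_tree <- function(dir) {
    files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
    stats::setNames(unname(tools::md5sum(files)),
                    sub(paste0("^", dir, "/"), "", files))
  }
  roots <- replicate(2, withr::local_tempdir(.local_envir = parent.frame()))
  trees <- purrr::map(roots, function(root) {
    sim <- file.path(root, "sim")
    out <- file.path(root, "out")
    rep <- file.path(root, "rep")
    run_cli("simulate", "--seed", "5", "--n-umcs", "2",
            "--trials-per-umc", "10", "--out", sim)
    run_cli("audit",
            "--trials-ctgov", file.path(sim, "trials_ctgov.csv"),
            "--trials-drks", file.path(sim, "trials_drks.csv"),
            "--publications", file.path(sim, "publications.csv"),
            "--links", file.path(sim, "links.csv"),
            "--oa", file.path(sim, "oa.csv"),
            "--tracker", file.path(sim, "tracker.csv"),
            "--out", out)
    run_cli("report", "--dataset", file.path(out, "dashboard.json"),
            "--out", rep)
    expect_true(file.exists(file.path(out, "summaries.csv")))
    expect_true(file.exists(file.path(out, "run.log")))
    expect_true(file.exists(file.path(rep, "index.html")))
    c(md5_tree(sim), md5_tree(out), md5_tree(rep))
  })
  expect_identical(trees[[1]], trees[[2]])

  # a missing column fails loudly with a non-zero exit and names the column
  bad <- file.path(roots[[1]], "bad.csv")
  readr::write_csv(tibble::tibble(nct_id = "NCT10000001"), bad)
  status <- suppressWarnings(system2(
    rscript,
    c(cli, "audit", "--trials-ctgov", bad,
      "--publications", bad, "--links", bad,
      "--out", file.path(roots[[1]], "nope")),
    stdout = TRUE, stderr = TRUE, env = libs
  ))
  expect_gt(attr(status, "status") %||% 0, 0)
  expect_true(any(grepl("completion_date|overall_status", status)))
})
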