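audit_of <- function(sets) {
  gd <- suppressMessages(build_graph(sets, "device"))
  gp <- suppressMessages(build_graph(sets, "patient"))
  res <- run_all_checks(gd, gp)
  list(report = summarize_audit(gd, gp, res), gd = gd, gp = gp, res = res)
}

test_that("duplicate reduction is 100 * (1 - post/pre) on combined term counts", {
  # five sets contribute 10 term mentions; 4 distinct labels remain -> 60%
  sets <- c(lapply(sprintf("S%d", 1:4), function(id)
    one_set(id, rr(id, "device", "C", "P"))),
    list(one_set("S5", rr("S5", "device", "C2", "P2"))))
  rep <- audit_of(sets)$report
  expect_identical(rep$device$terms$pre$combined, 10L)
  expect_identical(rep$device$terms$post$combined, 4L)
  expect_equal(rep$device$terms$reduction_pct, 60)
  expect_false(rep$device$terms$degenerate)
})

test_that("empty input yields an all-zero report flagged as degenerate", {
  rep <- audit_of(list())$report
  for (dom in c("device", "patient")) {
    expect_identical(rep[[dom]]$terms$post$combined, 0L)
    expect_equal(rep[[dom]]$terms$reduction_pct, 0)
    expect_true(rep[[dom]]$terms$degenerate)
    for (ck in rep[[dom]]$checks) {
      expect_identical(ck$pattern_count, 0L)
      expect_equal(ck$pct_of_combined_terms, 0)
    }
  }
  expect_identical(rep$cross_domain$count, 0L)
})

test_that("report fields equal the generator bookkeeping on a synthetic run", {
  gen <- generate_terminologies(synth_config(
    seed = 9, dual_role = 3, swaps = 2, multi_parent = 2,
    multi_parent_multiplicity = 4, cross_domain = 2))
  out <- audit_of(gen$sets)
  ck <- out$report$device$checks
  expect_identical(ck$dual_role$unique_term_count,
                   gen$expected$device$dual_role$unique_term_count)
  expect_identical(ck$swap$pattern_count, gen$expected$device$swap$pattern_count)
  expect_identical(ck$multi_parent$max_multiplicity, 4L)
  expect_identical(out$report$cross_domain$count, 2L)
  # percentages live in [0, 100]
  for (dom in c("device", "patient")) {
    for (c2 in out$report[[dom]]$checks) {
      expect_gte(c2$pct_of_combined_terms, 0)
      expect_lte(c2$pct_of_combined_terms, 100)
    }
    expect_lte(out$report[[dom]]$terms$post$combined,
               out$report[[dom]]$terms$pre$combined)
  }
})

test_that("JSON reports are byte-identical across runs and round-trip", {
  fx <- table_fixtures()
  sets <- c(fx$table2, fx$table4)  # vocabularies disjoint for 変形
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(audit_of(sets)$report, p1)
  write_report(audit_of(sets)$report, p2)
  expect_identical(readLines(p1, encoding = "UTF-8"),
                   readLines(p2, encoding = "UTF-8"))
  back <- read_report(p1)
  p3 <- withr::local_tempfile(fileext = ".json")
  write_report(back, p3)
  expect_identical(readLines(p1, encoding = "UTF-8"),
                   readLines(p3, encoding = "UTF-8"))
  expect_identical(back$device$checks$multi_parent$max_multiplicity, 11L)
})

test_that("top listings are sorted by multiplicity, then label", {
  fx <- table_fixtures()
  rep <- audit_of(fx$table4)$report
  top <- rep$device$checks$multi_parent$top
  expect_identical(top[[1]]$term, "変形")
  expect_identical(top[[1]]$multiplicity, 11L)
  mult <- vapply(top, `[[`, integer(1), "multiplicity")
  expect_identical(mult, sort(mult, decreasing = TRUE))
})

test_that("markdown and CSV renderings are written", {
  fx <- table_fixtures()
  rep <- audit_of(c(fx$table2, fx$table7))$report
  md <- withr::local_tempfile(fileext = ".md")
  write_report(rep, md, format = "markdown")
  text <- readLines(md, encoding = "UTF-8")
  expect_true(any(grepl("^## device problems", text)))
  expect_true(any(grepl("外傷", text)))  # the patient-domain 2-cycle is listed

  dir <- withr::local_tempdir()
  stem <- file.path(dir, "report.csv")
  write_report(rep, stem, format = "csv")
  expect_true(file.exists(file.path(dir, "report_terms.csv")))
  expect_true(file.exists(file.path(dir, "report_checks.csv")))
  checks <- utils::read.csv(file.path(dir, "report_checks.csv"))
  expect_identical(nrow(checks), 10L)  # 5 checks x 2 domains
})

test_that("findings export one row per pattern with provenance", {
  fx <- table_fixtures()
  out <- audit_of(fx$table2)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_findings(out$res, csv, "csv")
  df <- utils::read.csv(csv, colClasses = "character", fileEncoding = "UTF-8")
  expect_identical(sum(df$check_id == "dual_role" & df$domain == "device"),
                   out$res$device$dual_role$pattern_count)
  expect_true(any(df$check_id == "cycle" & df$domain == "patient"))
  expect_true(any(grepl("T2-A", df$provenance)))
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_findings(out$res, jl, "jsonl")
  lines <- readLines(jl, encoding = "UTF-8")
  expect_identical(length(lines), nrow(df))
  expect_silent(invisible(lapply(lines, jsonlite::fromJSON)))
})
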