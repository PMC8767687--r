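test_that("normalize_label strips edge whitespace and composes canonically", {
  expect_identical(normalize_label(" 破損 "), "破損")
  expect_identical(normalize_label("fuse blown"), "fuse blown")
  expect_identical(normalize_label("　不明"), "不明")  # ideographic space
  # NFD input composes to the same label as NFC input
  nfd <- stringi::stri_trans_nfd("早期放電")
  expect_identical(normalize_label(nfd), "早期放電")
  # internal width, case and punctuation are preserved
  expect_identical(normalize_label("ヒューズが切断すること。"),
                   "ヒューズが切断すること。")
  expect_identical(normalize_label("Ｍaterial"), "Ｍaterial")
  expect_error(normalize_label("  　 "), "empty")
})

test_that("normalize_label is idempotent on randomized strings", {
  set.seed(42)
  pieces <- c(" ", "　", "破", "損", "a", "B", "。", ",",
              stringi::stri_trans_nfd("が"), "x")
  for (i in 1:100) {
    s <- paste(sample(pieces, sample(2:8, 1), replace = TRUE), collapse = "")
    if (!nzchar(stringi::stri_trim_both(s))) next
    once <- normalize_label(s)
    expect_identical(normalize_label(once), once)
  }
})

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, con <- file(path, open = "w", encoding = "UTF-8"))
  close(con)
  path
}

csv_header <- "terminology_id,problem_domain,category_term,preferred_term,synonyms,definition,cdrh_ncit"

test_that("read_terminology_table groups rows into one set per terminology ID", {
  path <- write_tmp_csv(c(csv_header,
                          "A01-1,device,故障,バッテリ不良,,,",
                          "B02-1,patient,炎症,痛み,,,"))
  sets <- read_terminology_table(path)
  expect_length(sets, 2L)
  expect_identical(sets[[1]]$terminology_id, "A01-1")
  expect_identical(sets[[2]]$records[[1]]$problem_domain, "patient")
})

test_that("quoted intra-cell items survive the delimiter", {
  path <- write_tmp_csv(c(csv_header,
    'T1,patient,c1,穿孔,,,"""Vessels, perforation of"", cardiac perforation, perforation, injury"'))
  sets <- read_terminology_table(path)
  labs <- sets[[1]]$records[[1]]$cdrh_ncit_labels
  expect_length(labs, 4L)
  expect_true("Vessels, perforation of" %in% labs)
})

test_that("header-only file yields an empty list", {
  path <- write_tmp_csv(csv_header)
  expect_identical(read_terminology_table(path), list())
})

test_that("schema and value errors point at the problem", {
  path <- write_tmp_csv(c("terminology_id,problem_domain,category_term,preferred_term,synonyms,definition",
                          "T1,device,a,b,,"))
  expect_error(read_terminology_table(path), "cdrh_ncit")
  path2 <- write_tmp_csv(c(csv_header, "T1,gadget,a,b,,,"))
  expect_error(read_terminology_table(path2), "row 2")
  path3 <- write_tmp_csv(c(csv_header, "T1,device,a,b,,,", "T1,device,a,,,,"))
  expect_error(read_terminology_table(path3), "preferred term.*row 3")
})

test_that("repeated-row dialect collapses into one record", {
  path <- write_tmp_csv(c(csv_header,
                          "T1,device,cat,pref,syn1,def one,",
                          "T1,device,cat,pref,syn2,def one,"))
  sets <- read_terminology_table(path)
  expect_length(sets[[1]]$records, 1L)
  expect_setequal(sets[[1]]$records[[1]]$synonym_labels, c("syn1", "syn2"))
})

test_that("reading the same file twice is order-stable, and write/read round-trips", {
  fx <- table_fixtures()
  sets <- c(fx$table2, fx$table6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_terminology_table(sets, path)
  once <- read_terminology_table(path)
  twice <- read_terminology_table(path)
  expect_identical(once, twice)
  expect_identical(lapply(once, unclass), lapply(sets, unclass))
})

test_that("the Japanese seven-column layout reads with the default dialect", {
  path <- system.file("extdata", "worked_examples_ja.csv", package = "termaudit")
  sets <- read_terminology_table(path)
  expect_gt(length(sets), 20L)
  doms <- unlist(lapply(sets, function(s)
    vapply(s$records, `[[`, character(1), "problem_domain")))
  expect_setequal(unique(doms), c("device", "patient"))
  # identical content as the canonical-layout file
  canon <- read_terminology_table(
    system.file("extdata", "worked_examples.csv", package = "termaudit"))
  expect_identical(lapply(sets, function(s) lapply(s$records, unclass)),
                   lapply(canon, function(s) lapply(s$records, unclass)))
})

test_that("a dialect YAML overrides separators and headers", {
  dpath <- system.file("extdata", "dialect-example.yaml", package = "termaudit")
  d <- read_dialect(dpath)
  expect_s3_class(d, "table_dialect")
  expect_true("用語集ID" %in% d$header_map$terminology_id)
  path <- system.file("extdata", "worked_examples_ja.csv", package = "termaudit")
  expect_length(read_terminology_table(path, d), 25L)
})

test_that("validate_records collects issues without raising", {
  clean <- one_set("C1", rr("C1", "device", "cat", "pref", def = "a definition."))
  expect_identical(nrow(validate_records(list(clean))), 0L)

  dup <- terminology_set("D1", list(
    rr("D1", "device", "cat", "pref", def = "x."),
    rr("D1", "device", "cat", "pref", def = "x.")))
  issues <- validate_records(list(dup))
  expect_identical(issues$code, "duplicate-row")
  expect_identical(issues$severity, "warn")

  selfsyn <- one_set("E1", rr("E1", "device", "cat", "pref",
                              syn = c("pref", "other"), def = "x."))
  issues <- validate_records(list(selfsyn))
  expect_identical(issues$code, "self-synonym")
  expect_identical(issues$severity, "error")

  blank <- one_set("F1", rr("F1", "patient", "cat", "pref"))
  expect_identical(validate_records(list(blank))$code, "blank-definition")
})

test_that("record constructor enforces its invariants", {
  expect_error(term_record("", "device", "a", "b"), "terminology_id")
  expect_error(term_record("T", "device", " ", "b"), "empty")
  r <- rr("T", "device", "a", "b", syn = c("s", "s", "t"))
  expect_identical(r$synonym_labels, c("s", "t"))
  expect_error(terminology_set("T", list(rr("U", "device", "a", "b"))),
               "share")
})
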