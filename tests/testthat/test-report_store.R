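test_that("ingest joins drug and ADR rows to their report", {
  demo <- data.frame(report_id = c("A", "B", "C"),
                     age = c(70, 55, 41), sex = c("female", "male", "female"))
  drug <- data.frame(report_id = c("A", "A", "B", "C"),
                     substance_id = c(101L, 102L, 101L, 103L))
  adr <- data.frame(report_id = c("A", "B"), pt_code = c(201L, 202L))
  rs <- rs_from(demo, drug, adr)
  expect_equal(n_reports(rs), 3L)
  expect_equal(nrow(rs$drugs[rs$drugs$report_id == "A", ]), 2L)
  expect_equal(sort(rs$drugs[rs$drugs$report_id == "A", ]$substance_id),
               c(101L, 102L))
  expect_equal(rs$adrs$pt_code[rs$adrs$report_id == "B"], 202L)
})

test_that("rows referencing an unknown report are rejected, not fatal", {
  demo <- data.frame(report_id = c("A", "B"), age = c(70, 55),
                     sex = c("female", "male"))
  adr <- data.frame(report_id = c("A", "ZZZ"), pt_code = c(201L, 202L))
  rs <- rs_from(demo, adr = adr)
  expect_equal(n_reports(rs), 2L)
  expect_equal(rs$rejects$adr$report_id, "ZZZ")
  expect_false("ZZZ" %in% rs$adrs$report_id)
})

test_that("a missing required column raises a schema error naming it", {
  dir <- withr::local_tempdir()
  tabs <- make_tables(data.frame(report_id = "A", age = 70, sex = "female"))
  tabs$demo <- tabs$demo[, c("report_id", "age")] # drop sex
  write_report_tables(tabs, dir)
  expect_error(read_report_dir(dir), "sex", class = "pvic_schema_error")
  expect_error(read_report_dir(dir), "demo")
})

test_that("duplicated report ids in DEMO are refused", {
  demo <- data.frame(report_id = c("A", "A"), age = c(70, 71),
                     sex = c("female", "male"))
  expect_error(rs_from(demo), class = "pvic_schema_error")
})

test_that("write-then-read round-trips a generated report set", {
  dir <- withr::local_tempdir()
  gen <- generate_reports(generator_config(400, seed = 11), dir = dir)
  rs_disk <- read_report_dir(dir)
  rs_mem <- report_set_from_tables(gen$tables)
  for (part in c("demo", "drugs", "adrs")) {
    a <- as.data.frame(rs_disk[[part]])
    b <- as.data.frame(rs_mem[[part]])
    ord <- do.call(order, a)
    expect_equal(a[ord, ], b[do.call(order, b), ], ignore_attr = TRUE)
  }
})

test_that("duplicate exclusion is an exact set difference with provenance", {
  demo <- data.frame(report_id = sprintf("R%02d", 1:10),
                     age = rep(50, 10), sex = rep("male", 10))
  rs <- rs_from(demo)
  out <- exclude_duplicates(rs, c("R01", "R05", "R09"))
  expect_equal(n_reports(out), 7L)
  expect_false(any(c("R01", "R05", "R09") %in% out$demo$report_id))
  pv <- provenance(out)
  expect_equal(pv$n_removed[pv$step == "exclude_duplicates"], 3L)
  # empty duplicate list is the identity
  same <- exclude_duplicates(rs, character(0))
  expect_equal(same$demo, rs$demo)
  # unknown ids warn but do not error
  expect_warning(exclude_duplicates(rs, c("R02", "NOPE")),
                 "matched no stored report")
})

test_that("demographics filter keeps exactly the fully-known reports", {
  demo <- data.frame(report_id = c("A", "B", "C", "D"),
                     age = c("70", "NA", "55", "41"),
                     sex = c("female", "male", "NA", ""))
  rs <- rs_from(demo)
  out <- filter_known_demographics(rs)
  expect_equal(out$demo$report_id, "A")
  expect_equal(out$demo$age_years, 70)
  expect_equal(out$demo$sex, "female")
})

test_that("unknown encodings: sentinel values and age-group codes", {
  demo <- data.frame(report_id = c("A", "B", "C"),
                     age = c("3", "9", "5"), sex = c("F", "M", "9"))
  opts <- reader_options(unknown_values = c("", "NA", "9"),
                         age_group_map = c("3" = 35, "5" = 55))
  rs <- report_set_from_tables(make_tables(demo), options = opts)
  expect_equal(rs$demo$age_years, c(35, NA, 55))
  expect_equal(rs$demo$sex, c("female", "male", NA))
  out <- filter_known_demographics(rs)
  expect_equal(out$demo$report_id, "A")
})

test_that("generator bookkeeping: planted duplicate and unknown-demo rates", {
  gen <- generate_reports(generator_config(10000, seed = 303))
  rs <- report_set_from_tables(gen$tables)
  expect_equal(n_reports(rs), 10000L + gen$truth$n_duplicates)
  rs <- exclude_duplicates(rs, gen$tables$suspectedduplicates$report_id)
  expect_equal(n_reports(rs), gen$truth$n_clean)
  rs <- filter_known_demographics(rs)
  expect_equal(n_reports(rs), gen$truth$n_known_demo)
})

test_that("the two filters commute and are idempotent, provenance reconciles", {
  gen <- generate_reports(generator_config(2000, seed = 77))
  rs <- report_set_from_tables(gen$tables)
  dups <- gen$tables$suspectedduplicates$report_id
  a <- filter_known_demographics(exclude_duplicates(rs, dups))
  # demographics-first ordering may drop listed duplicates before the dedup
  # sees them; the resulting unmatched-id warning is expected here
  b <- suppressWarnings(exclude_duplicates(filter_known_demographics(rs), dups))
  expect_equal(a$demo, b$demo)
  expect_equal(a$drugs, b$drugs)
  expect_equal(a$adrs, b$adrs)
  twice <- filter_known_demographics(a)
  expect_equal(twice$demo, a$demo)
  suppressWarnings(twice2 <- exclude_duplicates(a, dups))
  expect_equal(twice2$demo, a$demo)
  pv <- provenance(a)
  expect_true(all(pv$n_in - pv$n_removed == pv$n_out))
  expect_equal(pv$n_out[-nrow(pv)], pv$n_in[-1])
  expect_equal(pv$n_out[nrow(pv)], n_reports(a))
})
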