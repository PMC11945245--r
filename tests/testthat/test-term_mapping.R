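test_that("exposure is set membership, counted once per report", {
  demo <- data.frame(report_id = c("A", "B", "C"),
                     age = c(60, 60, 60), sex = rep("female", 3))
  drug <- data.frame(report_id = c("A", "A", "B", "C", "C"),
                     substance_id = c(27193L, 99999L, 18514L, 27193L, 27193L))
  rs <- rs_from(demo, drug)
  sets <- load_term_config()
  all_icis <- sets$drug_sets$all_icis
  expect_equal(unname(resolve_exposure(rs, all_icis)), c(TRUE, TRUE, TRUE))
  # tremelimumab has two substance ids; either one confers exposure
  expect_equal(unname(resolve_exposure(rs, sets$drug_sets$tremelimumab)),
               c(FALSE, TRUE, FALSE))
  # two matching entries on one report still count once
  niv <- resolve_exposure(rs, sets$drug_sets$nivolumab)
  expect_equal(sum(niv), 2L)
  expect_true(niv[["C"]])
})

test_that("event resolution has set semantics over preferred terms", {
  sets <- load_term_config()
  frac <- sets$term_sets$fractures$pt_codes
  demo <- data.frame(report_id = c("A", "B"), age = c(60, 60),
                     sex = rep("male", 2))
  adr <- data.frame(report_id = c("A", "A", "A", "B"),
                    pt_code = c(frac[1], frac[2], frac[3], 424242L))
  rs <- rs_from(demo, adr = adr)
  ev <- resolve_event(rs, sets$term_sets$fractures)
  expect_equal(unname(ev), c(TRUE, FALSE))
  for (t in sets$term_sets)
    expect_false(resolve_event(rs, t)[["B"]])
})

test_that("the packaged config has the documented sets and cardinalities", {
  sets <- load_term_config()
  expect_length(sets$drug_sets, 7)
  expect_length(sets$term_sets, 3)
  expect_length(sets$term_sets$osteoporosis$pt_codes, 11)
  expect_length(sets$term_sets$hyperthyroidism$pt_codes, 19)
  expect_length(sets$term_sets$fractures$pt_codes, 78)
  expect_equal(sets$drug_sets$nivolumab$substance_ids, 27193L)
  expect_setequal(sets$drug_sets$tremelimumab$substance_ids,
                  c(18514L, 38501L))
  # the union set is exactly the union of the six single-agent sets
  expect_setequal(sets$drug_sets$all_icis$substance_ids,
                  unlist(lapply(sets$drug_sets[names(sets$drug_sets) != "all_icis"],
                                function(d) d$substance_ids)))
  expect_match(sets$term_sets$osteoporosis$grouping_source, "20000178")
})

test_that("config validation rejects malformed definitions", {
  dir <- withr::local_tempdir()
  write_cfg <- function(txt) {
    p <- file.path(dir, "cfg.yaml"); writeLines(txt, p); p
  }
  expect_error(load_term_config(write_cfg(c(
    "drug_sets:",
    "  - {name: a, substance_ids: [1]}",
    "  - {name: a, substance_ids: [2]}",
    "term_sets:",
    "  - {name: t, pt_codes: [9]}"))), "duplicate drug set name",
    class = "pvic_config_error")
  expect_error(load_term_config(write_cfg(c(
    "drug_sets:",
    "  - {name: a, substance_ids: []}",
    "term_sets:",
    "  - {name: t, pt_codes: [9]}"))), "'a'", class = "pvic_config_error")
  expect_error(load_term_config(write_cfg(c(
    "drug_sets:",
    "  - {name: a, substance_ids: [1]}",
    "term_sets:",
    "  - {name: t, pt_codes: [9.5]}"))), "'t'", class = "pvic_config_error")
  # an added set is simply returned
  base <- yaml::read_yaml(default_term_config())
  base$drug_sets[[8]] <- list(name = "extra", substance_ids = list(12345L))
  p <- file.path(dir, "cfg8.yaml")
  yaml::write_yaml(base, p)
  expect_length(load_term_config(p)$drug_sets, 8)
})

test_that("resolution is monotone in set definitions and unions are ORs", {
  rt <- random_tables(150, seed = 5)
  rs <- report_set_from_tables(rt$tables)
  small <- drug_set("small", 101L)
  big <- drug_set("big", c(101L, 99001L)) # enlarged set
  f_small <- resolve_exposure(rs, small)
  f_big <- resolve_exposure(rs, big)
  expect_true(all(f_big[f_small])) # enlarging never turns TRUE to FALSE
  other <- drug_set("other", 99001L)
  expect_equal(unname(f_big),
               unname(f_small | resolve_exposure(rs, other)))
  # same property for term sets
  t1 <- term_set("t1", 201L); t12 <- term_set("t12", c(201L, 202L))
  e1 <- resolve_event(rs, t1)
  expect_true(all(resolve_event(rs, t12)[e1]))
})

test_that("flag_reports returns one column per set in config order", {
  rt <- random_tables(40, seed = 6)
  rs <- report_set_from_tables(rt$tables)
  fl <- flag_reports(rs, list(tiny_drug_set()), list(tiny_term_set()))
  expect_named(fl, c("report_id", "exposed_target", "event_event"))
  expect_equal(fl$exposed_target, rt$exposed)
  expect_equal(fl$event_event, rt$event)
})
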