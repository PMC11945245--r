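# In-code fixture builders shared across test files.

# raw tables from minimal demo/drug/adr content; dictionaries are derived
# from the substance ids present (plus a filler substance)
make_tables <- function(demo,
                        drug = data.frame(report_id = character(),
                                          substance_id = integer()),
                        adr = data.frame(report_id = character(),
                                         pt_code = integer())) {
  subs <- sort(unique(c(as.integer(drug$substance_id), 99001L)))
  k <- seq_along(subs)
  mp_of <- stats::setNames(500000L + k, subs)
  list(
    demo = demo,
    drug = data.frame(report_id = drug$report_id,
                      drug_record_id = seq_len(nrow(drug)),
                      medicinalprod_id = unname(mp_of[as.character(drug$substance_id)])),
    adr = adr,
    mp = data.frame(medicinalprod_id = 500000L + k,
                    drug_name = paste0("drug_", subs),
                    sun_id = 600000L + k, atc_id = 700000L + k),
    sun = data.frame(sun_id = 600000L + k, substance_id = subs,
                     substance_name = paste0("sub_", subs)),
    atc = data.frame(atc_id = 700000L + k, atc_code = sprintf("A%02d", k)),
    suspectedduplicates = data.frame(report_id = character(0)))
}

rs_from <- function(demo, drug = data.frame(report_id = character(),
                                            substance_id = integer()),
                    adr = data.frame(report_id = character(),
                                     pt_code = integer())) {
  report_set_from_tables(make_tables(demo, drug, adr))
}

# a random small report population with known flags, for brute-force oracles
random_tables <- function(n, seed, p_expo = 0.3, p_evt = 0.25,
                          expo_sub = 101L, evt_pt = 201L) {
  set.seed(seed)
  ids <- sprintf("X%04d", seq_len(n))
  exposed <- runif(n) < p_expo
  event <- runif(n) < p_evt
  drug <- data.frame(
    report_id = c(ids[exposed], ids),
    substance_id = c(rep(expo_sub, sum(exposed)), rep(99001L, n)))
  adr <- data.frame(report_id = ids[event],
                    pt_code = rep(evt_pt, sum(event)))
  list(tables = make_tables(
         demo = data.frame(report_id = ids,
                           age = sample(20:90, n, replace = TRUE),
                           sex = sample(c("male", "female"), n, replace = TRUE)),
         drug = drug, adr = adr),
       exposed = exposed, event = event, ids = ids)
}

tiny_drug_set <- function() drug_set("target", 101L)
tiny_term_set <- function() term_set("event", 201L)
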