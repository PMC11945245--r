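#' Configuration for the synthetic report generator
#'
#' Defines a spontaneous-report population with known ground truth: clean
#' report count, demographic-missingness and duplicate-contamination rates,
#' per-drug-set exposure probabilities, per-term-set background event
#' probabilities, and drug–event association strengths. Association is
#' multiplicative on the event probability: a report exposed to drug set `S`
#' has event probability `lambda(S,T) * background(T)` for term set `T`
#' (products over multiply-exposed reports are clipped to 1), so `lambda = 1`
#' is exact independence and `log2(lambda)` is the large-sample target of the
#' information component.
#'
#' @param n_reports number of clean (non-duplicate) reports.
#' @param seed integer seed; the generator is fully reproducible given it.
#' @param p_unknown_demo probability a clean report has unknown age and/or
#'   sex (the missing field is chosen at random among age/sex/both).
#' @param p_duplicate duplicates added as a fraction of `n_reports`; each is
#'   a copy of a sampled clean report under a fresh id and is listed in the
#'   SUSPECTEDDUPLICATES table.
#' @param drug_marginals named numeric vector of exposure probabilities, one
#'   per generating drug set (defaults: 0.02 for each of the six packaged
#'   single-agent sets; union sets are never sampled directly).
#' @param event_marginals named numeric vector of background event
#'   probabilities per term set (defaults: osteoporosis 0.004,
#'   hyperthyroidism 0.003, fractures 0.012).
#' @param association named numeric vector of reporting-rate multipliers with
#'   names `"<drug_set>:<term_set>"`; unnamed pairs default to 1.
#' @param sets set definitions as returned by [load_term_config()].
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_reports,
                             seed = NULL,
                             p_unknown_demo = 0.12,
                             p_duplicate = 0.05,
                             drug_marginals = NULL,
                             event_marginals = NULL,
                             association = NULL,
                             sets = load_term_config()) {
  stopifnot(is_count(n_reports), n_reports >= 1)
  atomic <- setdiff(names(sets$drug_sets), "all_icis")
  if (is.null(drug_marginals))
    drug_marginals <- setNames(rep(0.02, length(atomic)), atomic)
  if (is.null(event_marginals))
    event_marginals <- c(osteoporosis = 0.004, hyperthyroidism = 0.003,
                         fractures = 0.012)[names(sets$term_sets)]
  probs <- c(p_unknown_demo, p_duplicate, drug_marginals, event_marginals)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop_pvic("all probabilities must lie in [0, 1]", "pvic_config_error")
  if (!all(names(drug_marginals) %in% names(sets$drug_sets)))
    stop_pvic("drug_marginals name a drug set not in the config",
              "pvic_config_error")
  if (!all(names(event_marginals) %in% names(sets$term_sets)))
    stop_pvic("event_marginals name a term set not in the config",
              "pvic_config_error")
  association <- association %||% numeric(0)
  if (length(association) && any(!is.finite(association) | association < 0))
    stop_pvic("association multipliers must be finite and >= 0",
              "pvic_config_error")
  for (nm in names(association)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% names(drug_marginals) ||
        !parts[2] %in% names(event_marginals))
      stop_pvic(sprintf("association name '%s' is not '<drug_set>:<term_set>'",
                        nm), "pvic_config_error")
    if (association[[nm]] * event_marginals[[parts[2]]] > 1)
      stop_pvic(sprintf(
        "pair '%s': lambda * background = %.3f exceeds 1; reduce the multiplier or the background rate",
        nm, association[[nm]] * event_marginals[[parts[2]]]),
        "pvic_config_error")
  }
  structure(list(n_reports = as.integer(n_reports), seed = seed,
                 p_unknown_demo = p_unknown_demo, p_duplicate = p_duplicate,
                 drug_marginals = drug_marginals,
                 event_marginals = event_marginals,
                 association = association, sets = sets),
            class = "generator_config")
}

# sample() treats a length-1 numeric first argument as 1:x; this does not
resample <- function(x, size) x[sample.int(length(x), size, replace = TRUE)]

lambda_of <- function(config, drug, term) {
  nm <- paste0(drug, ":", term)
  if (nm %in% names(config$association)) config$association[[nm]] else 1
}

# dictionary tables covering a vector of substance ids
make_dictionaries <- function(substance_ids, sets) {
  ids <- sort(unique(as.integer(substance_ids)))
  name_of <- rep(NA_character_, length(ids))
  for (d in sets$drug_sets) {
    hit <- ids %in% d$substance_ids & is.na(name_of)
    name_of[hit] <- d$name
  }
  name_of[is.na(name_of)] <- paste0("substance_", ids[is.na(name_of)])
  k <- seq_along(ids)
  list(
    mp = data.table(medicinalprod_id = 500000L + k,
                    drug_name = paste0("drug_", name_of),
                    sun_id = 600000L + k, atc_id = 700000L + k),
    sun = data.table(sun_id = 600000L + k, substance_id = ids,
                     substance_name = name_of),
    atc = data.table(atc_id = 700000L + k,
                     atc_code = sprintf("L01XC%02d", k)),
    mp_of = setNames(500000L + k, ids))
}

#' Generate a synthetic report dataset with planted truth
#'
#' Draws `n_reports` clean reports (demographics, per-drug-set exposure,
#' per-term-set events under the configured association model, plus filler
#' drug and ADR rows so the tables have realistic background content), then
#' adds duplicate copies and lists them in the SUSPECTEDDUPLICATES table.
#' The returned `truth` records everything a test needs to reconcile the
#' pipeline against the generator: the clean and demographics-known counts
#' and the exact contingency cells of every drug set / term set pair over
#' the post-filter population.
#'
#' @param config a [generator_config()].
#' @param dir optional output directory; when given, the seven raw tables are
#'   written as delimited files plus a `truth.json` sidecar.
#' @param delimiter field separator used when writing.
#' @return (invisibly) list with `tables` (named list of data.tables),
#'   `truth`, and `dir`.
#' @export
generate_reports <- function(config, dir = NULL, delimiter = "\t") {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_reports
  sets <- config$sets
  ids <- sprintf("R%07d", seq_len(n))

  age <- sample(18:95, n, replace = TRUE)
  sex <- ifelse(runif(n) < 0.5, "female", "male")
  unk <- runif(n) < config$p_unknown_demo
  mode <- sample(1:3, n, replace = TRUE) # 1 age, 2 sex, 3 both
  age[unk & mode != 2] <- NA
  sex[unk & mode != 1] <- NA

  drug_names <- names(config$drug_marginals)
  expo <- vapply(drug_names,
                 function(d) runif(n) < config$drug_marginals[[d]],
                 logical(n))
  if (is.null(dim(expo))) expo <- matrix(expo, nrow = n)
  colnames(expo) <- drug_names

  term_names <- names(config$event_marginals)
  evt <- matrix(FALSE, n, length(term_names),
                dimnames = list(NULL, term_names))
  for (t in term_names) {
    p <- rep(config$event_marginals[[t]], n)
    for (d in drug_names) {
      lam <- lambda_of(config, d, t)
      if (lam != 1) p[expo[, d]] <- p[expo[, d]] * lam
    }
    evt[, t] <- runif(n) < pmin(p, 1)
  }

  filler_sub <- 99001:99020
  filler_pt <- 98001:98050
  dict <- make_dictionaries(
    c(unlist(lapply(sets$drug_sets, `[[`, "substance_ids")), filler_sub),
    sets)

  # drug rows: one per exposed (report, set) + one background filler per report
  drug_rows <- list(data.table(report_id = ids,
                               substance_id = resample(filler_sub, n)))
  for (d in drug_names) {
    idx <- which(expo[, d])
    if (length(idx))
      drug_rows[[length(drug_rows) + 1L]] <- data.table(
        report_id = ids[idx],
        substance_id = resample(sets$drug_sets[[d]]$substance_ids,
                                length(idx)))
  }
  drug <- rbindlist(drug_rows)
  setorder(drug, report_id, substance_id)

  # ADR rows: one per event + background noise terms
  noise <- runif(n) < 0.5
  adr_rows <- list(data.table(report_id = ids[noise],
                              pt_code = resample(filler_pt, sum(noise))))
  for (t in term_names) {
    idx <- which(evt[, t])
    if (length(idx))
      adr_rows[[length(adr_rows) + 1L]] <- data.table(
        report_id = ids[idx],
        pt_code = resample(sets$term_sets[[t]]$pt_codes, length(idx)))
  }
  adr <- rbindlist(adr_rows)
  setorder(adr, report_id, pt_code)

  # duplicates: copies of sampled clean reports under fresh ids
  n_dup <- round(n * config$p_duplicate)
  dup_src <- if (n_dup > 0) sample.int(n, n_dup, replace = TRUE) else integer(0)
  dup_ids <- sprintf("D%07d", seq_len(n_dup))
  demo <- data.table(report_id = c(ids, dup_ids),
                     age = c(age, age[dup_src]),
                     sex = c(sex, sex[dup_src]))
  if (n_dup > 0) {
    dd <- drug[data.table(report_id = ids[dup_src], new_id = dup_ids),
               on = "report_id", allow.cartesian = TRUE, nomatch = NULL]
    dd[, report_id := new_id]; dd[, new_id := NULL]
    drug <- rbind(drug, dd)
    da <- adr[data.table(report_id = ids[dup_src], new_id = dup_ids),
              on = "report_id", allow.cartesian = TRUE, nomatch = NULL]
    da[, report_id := new_id]; da[, new_id := NULL]
    adr <- rbind(adr, da)
  }
  drug[, drug_record_id := seq_len(.N)]
  drug[, medicinalprod_id := dict$mp_of[as.character(substance_id)]]
  drug <- drug[, .(report_id, drug_record_id, medicinalprod_id)]

  # planted truth on the post-filter population (clean, demographics known)
  known <- !is.na(age) & !is.na(sex)
  cells <- list()
  for (dn in names(sets$drug_sets)) {
    sub_ids <- sets$drug_sets[[dn]]$substance_ids
    in_set <- vapply(drug_names, function(d)
      any(sets$drug_sets[[d]]$substance_ids %in% sub_ids), logical(1))
    ex <- if (sum(in_set) == 1) expo[, which(in_set)]
          else rowSums(expo[, in_set, drop = FALSE]) > 0
    for (tn in term_names) {
      ev <- evt[, tn]
      cells[[paste0(dn, ":", tn)]] <- c(
        n11 = sum(ex & ev & known), n10 = sum(ex & !ev & known),
        n01 = sum(!ex & ev & known), n00 = sum(!ex & !ev & known))
    }
  }
  truth <- list(n_clean = n, n_duplicates = n_dup,
                n_known_demo = sum(known), cells = cells,
                seed = config$seed)

  tables <- list(
    demo = demo,
    drug = drug,
    adr = adr,
    mp = dict$mp, sun = dict$sun, atc = dict$atc,
    suspectedduplicates = data.table(report_id = dup_ids))
  if (!is.null(dir)) {
    write_report_tables(tables, dir, delimiter)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(tables = tables, truth = truth, dir = dir))
}

#' Write raw report tables as delimited files
#'
#' @param tables named list with elements demo, drug, adr, mp, sun, atc,
#'   suspectedduplicates.
#' @param dir output directory (created if needed).
#' @param delimiter field separator.
#' @return (invisibly) named vector of file paths.
#' @export
write_report_tables <- function(tables, dir, delimiter = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("demo", "drug", "adr", "mp", "sun", "atc",
               "suspectedduplicates")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    fwrite(tables[[nm]], p, sep = delimiter, na = "NA", quote = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

# shared by tests and the pipeline: read a directory written by the generator
#' Read a generator output directory into a report set
#' @param dir directory written by [generate_reports()] or [plant_exact()].
#' @param options a [reader_options()] object.
#' @return a `report_set`.
#' @export
read_report_dir <- function(dir, options = reader_options()) {
  read_report_tables(file.path(dir, "demo.tsv"), file.path(dir, "drug.tsv"),
                     file.path(dir, "adr.tsv"),
                     dictionary_paths = list(mp = file.path(dir, "mp.tsv"),
                                             sun = file.path(dir, "sun.tsv"),
                                             atc = file.path(dir, "atc.tsv")),
                     options = options)
}

#' Specification of an exact planted contingency table
#'
#' @param drug_set,term_set names of the target sets (must exist in the set
#'   config used at planting time).
#' @param n11,n10,n01,n00 target cell counts after the standard
#'   ingest-and-filter path.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(drug_set, term_set, n11, n10, n01, n00) {
  for (v in list(n11, n10, n01, n00))
    if (!is_count(v)) stop_pvic("plant cells must be non-negative integers",
                                "pvic_config_error")
  if (n11 + n10 + n01 + n00 < 1)
    stop_pvic("plant cells must sum to at least 1", "pvic_config_error")
  structure(list(drug_set = drug_set, term_set = term_set,
                 n11 = n11, n10 = n10, n01 = n01, n00 = n00),
            class = "plant_spec")
}

#' Plant a dataset that reproduces an exact contingency table
#'
#' Emits raw tables which, after the standard ingest, deduplication and
#' demographics filters, yield exactly the requested cells for the given
#' drug set / term set pair. Construction is run-length (each cell a
#' contiguous block of reports), so paper-scale tables are feasible;
#' `scale_divisor > 1` shrinks every cell proportionally with exact integer
#' arithmetic and errors if any cell is not divisible.
#'
#' @param spec a [plant_spec()].
#' @param dir optional output directory (tables + `truth.json`).
#' @param scale_divisor positive integer divisor applied to all four cells.
#' @param sets set definitions; the spec's set names must resolve here.
#' @param delimiter field separator used when writing.
#' @return (invisibly) list with `tables`, `truth` and `dir`.
#' @export
plant_exact <- function(spec, dir = NULL, scale_divisor = 1,
                        sets = load_term_config(), delimiter = "\t") {
  stopifnot(inherits(spec, "plant_spec"), is_count(scale_divisor),
            scale_divisor >= 1)
  cells <- c(n11 = spec$n11, n10 = spec$n10, n01 = spec$n01, n00 = spec$n00)
  bad <- cells %% scale_divisor != 0
  if (any(bad))
    stop_pvic(sprintf("cells not divisible by %d: %s", scale_divisor,
                      paste(names(cells)[bad], collapse = ", ")),
              "pvic_config_error")
  cells <- cells %/% scale_divisor
  ds <- sets$drug_sets[[spec$drug_set]]
  ts <- sets$term_sets[[spec$term_set]]
  if (is.null(ds) || is.null(ts))
    stop_pvic(sprintf("unknown set name(s): %s / %s",
                      spec$drug_set, spec$term_set), "pvic_config_error")
  n <- sum(cells)
  ids <- sprintf("P%08d", seq_len(n))
  # blocks in order n11, n10, n01, n00
  exposed <- rep(c(TRUE, TRUE, FALSE, FALSE), cells)
  event <- rep(c(TRUE, FALSE, TRUE, FALSE), cells)
  filler_sub <- 99001L
  dict <- make_dictionaries(c(ds$substance_ids, filler_sub), sets)
  sub <- ifelse(exposed, ds$substance_ids[1], filler_sub)
  drug <- data.table(report_id = ids,
                     drug_record_id = seq_len(n),
                     medicinalprod_id = dict$mp_of[as.character(sub)])
  adr <- data.table(report_id = ids[event], pt_code = ts$pt_codes[1])
  demo <- data.table(report_id = ids, age = 60L,
                     sex = rep_len(c("female", "male"), n))
  tables <- list(demo = demo, drug = drug, adr = adr,
                 mp = dict$mp, sun = dict$sun, atc = dict$atc,
                 suspectedduplicates = data.table(report_id = character(0)))
  truth <- list(cells = as.list(cells), drug_set = spec$drug_set,
                term_set = spec$term_set, scale_divisor = scale_divisor)
  if (!is.null(dir)) {
    write_report_tables(tables, dir, delimiter)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(tables = tables, truth = truth, dir = dir))
}

#' Generate a regression cohort of drug-exposed reports with known
#' coefficients
#'
#' Every generated report is exposed to one of the single-agent drug sets;
#' binary covariates (age 65+, female, osteoporosis term, hyperthyroidism
#' term) are drawn from the configured prevalences and the fracture outcome
#' from a logistic model with the supplied true coefficients. Covariates are
#' encoded in the raw tables exactly as the pipeline expects them (ages,
#' sexes and term codes), so [build_design()] recovers the planted flags.
#'
#' @param n_reports cohort size.
#' @param truth named numeric vector of true log-odds coefficients:
#'   `(Intercept)`, `age65`, `female`, `osteoporosis`, `hyperthyroidism`.
#' @param prevalence named numeric vector of covariate prevalences.
#' @param seed integer seed.
#' @param sets set definitions.
#' @param dir optional output directory (tables + `truth.json`).
#' @return (invisibly) list with `tables`, `truth` (coefficients, flags,
#'   prevalence) and `dir`.
#' @export
generate_cohort_for_regression <- function(
    n_reports,
    truth = c(`(Intercept)` = -4, age65 = 0.5, female = 0.45,
              osteoporosis = log(118), hyperthyroidism = 0),
    prevalence = c(age65 = 0.45, female = 0.45, osteoporosis = 0.02,
                   hyperthyroidism = 0.015),
    seed = NULL, sets = load_term_config(), dir = NULL) {
  stopifnot(is_count(n_reports), n_reports >= 1)
  need <- c("(Intercept)", "age65", "female", "osteoporosis",
            "hyperthyroidism")
  if (!all(need %in% names(truth)))
    stop_pvic(sprintf("truth must name coefficients: %s",
                      paste(need, collapse = ", ")), "pvic_config_error")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_reports)
  ids <- sprintf("C%07d", seq_len(n))
  age65 <- runif(n) < prevalence[["age65"]]
  female <- runif(n) < prevalence[["female"]]
  osteo <- runif(n) < prevalence[["osteoporosis"]]
  hyper <- runif(n) < prevalence[["hyperthyroidism"]]
  lp <- truth[["(Intercept)"]] + truth[["age65"]] * age65 +
    truth[["female"]] * female + truth[["osteoporosis"]] * osteo +
    truth[["hyperthyroidism"]] * hyper
  fracture <- runif(n) < plogis(lp)

  atomic <- setdiff(names(sets$drug_sets), "all_icis")
  which_drug <- sample(atomic, n, replace = TRUE)
  sub <- vapply(sets$drug_sets[which_drug],
                function(d) d$substance_ids[1], integer(1))
  dict <- make_dictionaries(
    unlist(lapply(sets$drug_sets, `[[`, "substance_ids")), sets)
  demo <- data.table(report_id = ids,
                     age = ifelse(age65, sample(65:90, n, replace = TRUE),
                                  sample(20:64, n, replace = TRUE)),
                     sex = ifelse(female, "female", "male"))
  drug <- data.table(report_id = ids, drug_record_id = seq_len(n),
                     medicinalprod_id = unname(dict$mp_of[as.character(sub)]))
  pt_of <- function(set_name, flag)
    data.table(report_id = ids[flag],
               pt_code = resample(sets$term_sets[[set_name]]$pt_codes,
                                  sum(flag)))
  adr <- rbindlist(list(pt_of("osteoporosis", osteo),
                        pt_of("hyperthyroidism", hyper),
                        pt_of("fractures", fracture)))
  setorder(adr, report_id, pt_code)
  tables <- list(demo = demo, drug = drug, adr = adr,
                 mp = dict$mp, sun = dict$sun, atc = dict$atc,
                 suspectedduplicates = data.table(report_id = character(0)))
  truth_out <- list(
    coefficients = as.list(truth), prevalence = as.list(prevalence),
    n = n, n_fracture = sum(fracture),
    flags = data.table(report_id = ids, outcome = fracture, age65 = age65,
                       female = female, osteoporosis = osteo,
                       hyperthyroidism = hyper))
  if (!is.null(dir)) {
    write_report_tables(tables, dir)
    jsonlite::write_json(truth_out[c("coefficients", "prevalence", "n",
                                     "n_fracture")],
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(tables = tables, truth = truth_out, dir = dir))
}

# in-memory shortcut used heavily in tests and simulations: raw tables ->
# report_set without touching disk
#' Assemble a report set directly from in-memory raw tables
#' @param tables named list as produced by the generators.
#' @param options a [reader_options()] object.
#' @return a `report_set`.
#' @export
report_set_from_tables <- function(tables, options = reader_options()) {
  build_report_set(tables$demo, tables$drug, tables$adr, tables$mp,
                   tables$sun, tables$atc, options)
}
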