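#' Define a drug (exposure) set
#'
#' A named set of substance ids. A report is exposed to the set if any of its
#' drug rows carries one of these ids; a substance may belong to several sets
#' (a single agent and an all-drugs-of-class union, for instance).
#'
#' @param name set label.
#' @param substance_ids non-empty vector of integer substance codes.
#' @return an object of class `drug_set`.
#' @export
drug_set <- function(name, substance_ids) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop_pvic("drug set name must be a non-empty string", "pvic_config_error")
  ids <- suppressWarnings(as.integer(substance_ids))
  if (length(ids) == 0 || anyNA(ids) ||
      any(as.numeric(substance_ids) != ids))
    stop_pvic(sprintf("drug set '%s': substance_ids must be a non-empty set of integers",
                      name), "pvic_config_error")
  structure(list(name = name, substance_ids = unique(ids)), class = "drug_set")
}

#' Define an adverse-event term set
#'
#' A named flat set of preferred-term codes. `grouping_source` records where
#' the list came from (an SMQ or a term-hierarchy grouping); it is provenance
#' only and never used in computation.
#'
#' @param name set label.
#' @param pt_codes non-empty vector of integer preferred-term codes.
#' @param grouping_source optional provenance label.
#' @return an object of class `term_set`.
#' @export
term_set <- function(name, pt_codes, grouping_source = NA_character_) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop_pvic("term set name must be a non-empty string", "pvic_config_error")
  codes <- suppressWarnings(as.integer(pt_codes))
  if (length(codes) == 0 || anyNA(codes) ||
      any(as.numeric(pt_codes) != codes))
    stop_pvic(sprintf("term set '%s': pt_codes must be a non-empty set of integers",
                      name), "pvic_config_error")
  structure(list(name = name, pt_codes = unique(codes),
                 grouping_source = as.character(grouping_source)),
            class = "term_set")
}

#' @export
print.drug_set <- function(x, ...) {
  cat(sprintf("<drug_set> %s: %d substance id(s)\n", x$name,
              length(x$substance_ids)))
  invisible(x)
}

#' @export
print.term_set <- function(x, ...) {
  cat(sprintf("<term_set> %s: %d preferred-term code(s) [%s]\n", x$name,
              length(x$pt_codes), x$grouping_source))
  invisible(x)
}

#' Load drug-set and term-set definitions from a YAML config
#'
#' The config has two blocks: `drug_sets:` (entries with `name` and
#' `substance_ids`) and `term_sets:` (entries with `name`, `grouping_source`
#' and `pt_codes`). Set names must be unique within each block; empty sets
#' and non-integer codes are rejected with the offending entry named.
#'
#' @param path path to the YAML file; defaults to the packaged fixture config
#'   (see [default_term_config()]).
#' @return list with elements `drug_sets` and `term_sets`, each a named list.
#' @export
load_term_config <- function(path = default_term_config()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$drug_sets) || is.null(cfg$term_sets))
    stop_pvic("config must contain 'drug_sets' and 'term_sets' blocks",
              "pvic_config_error")
  dsets <- lapply(cfg$drug_sets, function(d)
    drug_set(d$name %||% "", d$substance_ids))
  tsets <- lapply(cfg$term_sets, function(t)
    term_set(t$name %||% "", t$pt_codes, t$grouping_source %||% NA_character_))
  dn <- vapply(dsets, `[[`, "", "name")
  tn <- vapply(tsets, `[[`, "", "name")
  if (anyDuplicated(dn))
    stop_pvic(sprintf("duplicate drug set name: %s", dn[duplicated(dn)][1]),
              "pvic_config_error")
  if (anyDuplicated(tn))
    stop_pvic(sprintf("duplicate term set name: %s", tn[duplicated(tn)][1]),
              "pvic_config_error")
  list(drug_sets = setNames(dsets, dn), term_sets = setNames(tsets, tn))
}

#' Path to the packaged default set definitions
#'
#' The shipped config defines the six checkpoint-inhibitor drug sets by their
#' real substance ids plus their union set, and three adverse-event term sets
#' (osteoporosis, hyperthyroidism, fractures) with fixture preferred-term
#' codes of the correct cardinalities (11, 19 and 78; the fracture list in
#' six term-group blocks). Real dictionary PT codes are licensed and are
#' supplied by the user as a drop-in replacement config.
#'
#' @return path to the YAML file installed with the package.
#' @export
default_term_config <- function() {
  system.file("extdata", "term_sets.yaml", package = "pvic", mustWork = TRUE)
}

#' Exposure status of each report against a drug set
#'
#' A report is exposed if at least one of its drug rows carries a substance
#' id in the set; multiple matching rows still count the report once.
#'
#' @param reports a `report_set`.
#' @param drug_set a [drug_set()].
#' @return named logical vector, one element per report (names are report
#'   ids), in the report set's order.
#' @export
resolve_exposure <- function(reports, drug_set) {
  stopifnot(inherits(reports, "report_set"), inherits(drug_set, "drug_set"))
  hit <- unique(reports$drugs[substance_id %in% drug_set$substance_ids,
                              report_id])
  setNames(reports$demo$report_id %in% hit, reports$demo$report_id)
}

#' Event status of each report against a term set
#'
#' A report has the event if at least one of its ADR rows carries a
#' preferred-term code in the set; multiple matching terms count once.
#'
#' @param reports a `report_set`.
#' @param term_set a [term_set()].
#' @return named logical vector, one element per report.
#' @export
resolve_event <- function(reports, term_set) {
  stopifnot(inherits(reports, "report_set"), inherits(term_set, "term_set"))
  hit <- unique(reports$adrs[pt_code %in% term_set$pt_codes, report_id])
  setNames(reports$demo$report_id %in% hit, reports$demo$report_id)
}

#' Exposure and event flags for every report
#'
#' @param reports a `report_set`.
#' @param drug_sets,term_sets named lists as returned by [load_term_config()].
#' @return data.table with `report_id`, one logical `exposed_<set>` column
#'   per drug set and one logical `event_<set>` column per term set.
#' @export
flag_reports <- function(reports, drug_sets, term_sets) {
  stopifnot(inherits(reports, "report_set"))
  out <- data.table(report_id = reports$demo$report_id)
  for (d in drug_sets)
    out[, paste0("exposed_", d$name) := unname(resolve_exposure(reports, d))]
  for (t in term_sets)
    out[, paste0("event_", t$name) := unname(resolve_event(reports, t))]
  out[]
}
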