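#' Reader options for raw report tables
#'
#' Spontaneous-report extracts come in several dialects: delimiters differ and
#' unknown demographics may be encoded as an empty field, the literal string
#' `"NA"`, or a site-specific sentinel code. These options control how the
#' raw tables are parsed into a [report_set].
#'
#' @param delimiter single-character field separator (`"\t"` or `","`).
#' @param unknown_values character vector of field values (after trimming)
#'   that encode an unknown age or sex.
#' @param age_group_map optional named numeric vector mapping age-group codes
#'   (as they appear in the file) to midpoint ages in years. When `NULL`,
#'   the age column is parsed as numeric years directly.
#' @return a list of class `pvic_reader_options`.
#' @export
reader_options <- function(delimiter = "\t",
                           unknown_values = c("", "NA"),
                           age_group_map = NULL) {
  stopifnot(is.character(delimiter), nchar(delimiter) == 1)
  if (!is.null(age_group_map) &&
      (is.null(names(age_group_map)) || !is.numeric(age_group_map)))
    stop("age_group_map must be a named numeric vector (code -> midpoint years)")
  structure(list(delimiter = delimiter,
                 unknown_values = unknown_values,
                 age_group_map = age_group_map),
            class = "pvic_reader_options")
}

# required columns per raw table
.schema <- list(
  demo = c("report_id", "age", "sex"),
  drug = c("report_id", "drug_record_id", "medicinalprod_id"),
  adr  = c("report_id", "pt_code"),
  mp   = c("medicinalprod_id", "drug_name", "sun_id", "atc_id"),
  sun  = c("sun_id", "substance_id", "substance_name"),
  atc  = c("atc_id", "atc_code")
)

assert_columns <- function(dt, table_name, file = table_name) {
  missing <- setdiff(.schema[[table_name]], names(dt))
  if (length(missing))
    stop_pvic(sprintf("table '%s' is missing required column(s): %s",
                      file, paste(missing, collapse = ", ")),
              "pvic_schema_error")
  invisible(dt)
}

parse_sex <- function(x, unknown_values) {
  x <- trimws(as.character(x))
  x[x %in% unknown_values] <- NA_character_
  low <- tolower(x)
  out <- rep(NA_character_, length(x))
  out[low %in% c("male", "m", "1")] <- "male"
  out[low %in% c("female", "f", "2")] <- "female"
  out
}

parse_age <- function(x, options) {
  x <- trimws(as.character(x))
  x[x %in% options$unknown_values] <- NA_character_
  if (!is.null(options$age_group_map)) {
    mapped <- options$age_group_map[x]
    return(unname(mapped))
  }
  suppressWarnings(as.numeric(x))
}

new_report_set <- function(demo, drugs, adrs, provenance, rejects) {
  x <- structure(list(demo = demo, drugs = drugs, adrs = adrs,
                      provenance = provenance, rejects = rejects),
                 class = "report_set")
  validate_report_set(x)
}

validate_report_set <- function(x) {
  if (anyDuplicated(x$demo$report_id))
    stop_pvic("duplicate report_id in report set", "pvic_invariant_error")
  pv <- x$provenance
  if (nrow(pv)) {
    if (any(pv$n_in - pv$n_removed != pv$n_out))
      stop_pvic("provenance counts do not reconcile (n_in - n_removed != n_out)",
                "pvic_invariant_error")
    if (nrow(pv) > 1 && any(pv$n_out[-nrow(pv)] != pv$n_in[-1]))
      stop_pvic("provenance chain broken: a step's output is not the next step's input",
                "pvic_invariant_error")
    if (pv$n_out[nrow(pv)] != nrow(x$demo))
      stop_pvic("provenance final count does not match stored reports",
                "pvic_invariant_error")
  }
  x
}

add_provenance <- function(x, step, n_in, n_removed) {
  x$provenance <- rbind(x$provenance,
                        data.table(step = step, n_in = n_in,
                                   n_removed = n_removed,
                                   n_out = n_in - n_removed))
  x
}

# assemble a report_set from already-parsed in-memory tables; shared by the
# file reader and the synthetic generator (which round-trips without disk)
build_report_set <- function(demo, drug, adr, mp, sun, atc = NULL,
                             options = reader_options()) {
  demo <- as.data.table(demo); drug <- as.data.table(drug)
  adr <- as.data.table(adr); mp <- as.data.table(mp); sun <- as.data.table(sun)
  assert_columns(demo, "demo"); assert_columns(drug, "drug")
  assert_columns(adr, "adr"); assert_columns(mp, "mp"); assert_columns(sun, "sun")
  if (!is.null(atc)) { atc <- as.data.table(atc); assert_columns(atc, "atc") }

  if (anyDuplicated(demo$report_id))
    stop_pvic("DEMO table contains duplicated report_id values",
              "pvic_schema_error")

  demo <- data.table(report_id = as.character(demo$report_id),
                     age_years = parse_age(demo$age, options),
                     sex       = parse_sex(demo$sex, options$unknown_values))
  neg <- !is.na(demo$age_years) & demo$age_years < 0
  if (any(neg))
    stop_pvic("DEMO table contains negative ages", "pvic_schema_error")

  drug[, report_id := as.character(report_id)]
  adr[, report_id := as.character(report_id)]
  adr[, pt_code := as.integer(pt_code)]
  if (any(is.na(adr$pt_code) | adr$pt_code < 0))
    stop_pvic("ADR table contains missing or negative pt_code values",
              "pvic_schema_error")

  # Modified DRUG table: left-join dictionaries; unmatched keys keep the raw
  # id with absent names
  mdrug <- merge(drug, mp, by = "medicinalprod_id", all.x = TRUE, sort = FALSE)
  mdrug <- merge(mdrug, sun, by = "sun_id", all.x = TRUE, sort = FALSE)
  if (!is.null(atc)) {
    mdrug <- merge(mdrug, atc, by = "atc_id", all.x = TRUE, sort = FALSE)
  } else {
    mdrug[, atc_code := NA_character_]
  }
  mdrug[, substance_id := as.integer(substance_id)]
  mdrug[, drug_record_id := as.character(drug_record_id)]
  mdrug[, medicinalprod_id := as.character(medicinalprod_id)]
  mdrug <- mdrug[, .(report_id, drug_record_id, medicinalprod_id,
                     substance_id, substance_name, atc_code, drug_name)]

  # referential integrity: drug/ADR rows pointing at no DEMO report are
  # collected, not fatal
  known <- demo$report_id
  rejects <- list(drug = mdrug[!report_id %in% known],
                  adr  = adr[!report_id %in% known])
  mdrug <- mdrug[report_id %in% known]
  adr <- adr[report_id %in% known]

  prov <- data.table(step = "ingest", n_in = nrow(demo), n_removed = 0L,
                     n_out = nrow(demo))
  new_report_set(demo, mdrug, adr, prov, rejects)
}

#' Read raw report tables into a report set
#'
#' Ingests a VigiBase-style relational extract: one DEMO row per case report,
#' DRUG and ADR rows linked by `report_id`, and the MP/SUN/ATC dictionary
#' tables joined onto the drug rows (left joins; a `medicinalprod_id` absent
#' from MP keeps the raw id with missing substance and names). Drug or ADR
#' rows whose `report_id` does not appear in DEMO are collected into
#' `rejects` rather than aborting the read.
#'
#' @param demo_path,drug_path,adr_path paths to the DEMO, DRUG and ADR tables.
#' @param dictionary_paths named list with elements `mp`, `sun` and optionally
#'   `atc`, paths to the dictionary tables.
#' @param options a [reader_options()] object.
#' @return a `report_set`: parsed `demo` (report_id, age_years, sex with `NA`
#'   for unknown), joined `drugs`, `adrs`, a `provenance` table of filter
#'   counts, and `rejects` holding orphan rows.
#' @export
read_report_tables <- function(demo_path, drug_path, adr_path,
                               dictionary_paths,
                               options = reader_options()) {
  for (p in c(demo_path, drug_path, adr_path,
              unlist(dictionary_paths, use.names = FALSE)))
    if (!file.exists(p))
      stop_pvic(sprintf("input file not found: %s", p), "pvic_io_error")
  rd <- function(p) fread(p, sep = options$delimiter, colClasses = "character",
                          na.strings = NULL)
  demo <- rd(demo_path); drug <- rd(drug_path); adr <- rd(adr_path)
  assert_columns(demo, "demo", demo_path)
  assert_columns(drug, "drug", drug_path)
  assert_columns(adr, "adr", adr_path)
  mp <- rd(dictionary_paths$mp); sun <- rd(dictionary_paths$sun)
  assert_columns(mp, "mp", dictionary_paths$mp)
  assert_columns(sun, "sun", dictionary_paths$sun)
  atc <- if (!is.null(dictionary_paths$atc)) {
    a <- rd(dictionary_paths$atc); assert_columns(a, "atc", dictionary_paths$atc); a
  }
  build_report_set(demo, drug, adr, mp, sun, atc, options)
}

#' Read a SUSPECTEDDUPLICATES table
#'
#' @param path path to a delimited file with a `report_id` column.
#' @param options a [reader_options()] object (delimiter only).
#' @return character vector of suspected-duplicate report ids.
#' @export
read_duplicate_ids <- function(path, options = reader_options()) {
  dt <- fread(path, sep = options$delimiter, colClasses = "character",
              na.strings = NULL)
  if (!"report_id" %in% names(dt))
    stop_pvic(sprintf("table '%s' is missing required column(s): report_id", path),
              "pvic_schema_error")
  unique(dt$report_id)
}

#' Exclude suspected duplicate reports
#'
#' Removes every report whose id appears in the supplied suspected-duplicate
#' list. The list is an input (produced upstream by the database provider's
#' statistical duplicate-detection algorithm); ids in the list that match no
#' stored report only raise a warning count.
#'
#' @param reports a `report_set`.
#' @param duplicate_ids character vector of report ids to drop (see
#'   [read_duplicate_ids()]).
#' @return the filtered `report_set`, with a provenance row appended.
#' @export
exclude_duplicates <- function(reports, duplicate_ids) {
  stopifnot(inherits(reports, "report_set"))
  duplicate_ids <- as.character(duplicate_ids)
  n_in <- nrow(reports$demo)
  hit <- reports$demo$report_id %in% duplicate_ids
  unmatched <- length(setdiff(duplicate_ids, reports$demo$report_id))
  if (unmatched > 0)
    warning(sprintf("%d duplicate id(s) matched no stored report", unmatched))
  keep <- reports$demo$report_id[!hit]
  reports$demo <- reports$demo[!hit]
  reports$drugs <- reports$drugs[report_id %in% keep]
  reports$adrs <- reports$adrs[report_id %in% keep]
  validate_report_set(add_provenance(reports, "exclude_duplicates",
                                     n_in, sum(hit)))
}

#' Keep only reports with known age and sex
#'
#' Retains exactly the reports whose sex is recorded as male or female and
#' whose age in years is known, mirroring the standard demographic-complete
#' analysis population used in disproportionality studies.
#'
#' @param reports a `report_set`.
#' @return the filtered `report_set`, with a provenance row appended.
#' @export
filter_known_demographics <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  n_in <- nrow(reports$demo)
  drop <- is.na(reports$demo$age_years) | is.na(reports$demo$sex)
  keep <- reports$demo$report_id[!drop]
  reports$demo <- reports$demo[!drop]
  reports$drugs <- reports$drugs[report_id %in% keep]
  reports$adrs <- reports$adrs[report_id %in% keep]
  validate_report_set(add_provenance(reports, "filter_known_demographics",
                                     n_in, sum(drop)))
}

#' Number of reports in a report set
#' @param x a `report_set`.
#' @return integer count of case reports.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "report_set"))
  nrow(x$demo)
}

#' Filter provenance of a report set
#' @param x a `report_set`.
#' @return data.table with columns step, n_in, n_removed, n_out.
#' @export
provenance <- function(x) {
  stopifnot(inherits(x, "report_set"))
  copy(x$provenance)
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d reports, %d drug rows, %d ADR rows\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$adrs)))
  if (nrow(x$provenance)) {
    cat("provenance:\n")
    print(x$provenance, row.names = FALSE)
  }
  nrej <- nrow(x$rejects$drug) + nrow(x$rejects$adr)
  if (nrej) cat(sprintf("rejected orphan rows: %d\n", nrej))
  invisible(x)
}
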