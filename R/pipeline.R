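#' Run configuration for the end-to-end pipeline
#'
#' @param demo,drug,adr paths to the DEMO, DRUG and ADR tables.
#' @param mp,sun,atc dictionary table paths (`atc` optional).
#' @param duplicates path to the SUSPECTEDDUPLICATES table, or `NULL` to skip
#'   deduplication.
#' @param term_config path to the drug/term set YAML (default: packaged
#'   fixture config).
#' @param out_dir directory for `signals.csv`, `regression.csv` and
#'   `manifest.json`.
#' @param priors a [bcpnn_priors()] object.
#' @param regression_sets names of the drug set, outcome term set and the two
#'   covariate term sets used for the logistic model.
#' @param report_zero_n11 emit computed IC values for `n11 = 0` rows?
#' @param options a [reader_options()] object.
#' @return a list of class `run_config`.
#' @export
run_config <- function(demo, drug, adr, mp, sun, atc = NULL,
                       duplicates = NULL,
                       term_config = default_term_config(),
                       out_dir = ".",
                       priors = bcpnn_priors(),
                       regression_sets = c(drug_set = "all_icis",
                                           outcome = "fractures",
                                           covariate1 = "osteoporosis",
                                           covariate2 = "hyperthyroidism"),
                       report_zero_n11 = FALSE,
                       options = reader_options()) {
  structure(list(demo = demo, drug = drug, adr = adr, mp = mp, sun = sun,
                 atc = atc, duplicates = duplicates,
                 term_config = term_config, out_dir = out_dir,
                 priors = priors, regression_sets = regression_sets,
                 report_zero_n11 = report_zero_n11, options = options),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_pvic(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "pvic_stage_error")
  })
}

# format a numeric column at 6 significant digits for stable csv output
fmt6 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.6g", x))

#' Run the full disproportionality workflow
#'
#' Executes ingest, duplicate exclusion, demographics filtering, set mapping,
#' contingency construction, IC signal screening over every drug set / term
#' set pair, and the covariate-adjusted logistic regression of the outcome
#' term set among exposed reports. Outputs are deterministic given identical
#' inputs and config: `signals.csv` (one row per pair, full-precision
#' 6-significant-digit columns plus 2-decimal display columns),
#' `regression.csv`, and `manifest.json` recording package version, config
#' hash, input checksums and filter provenance. Any stage error aborts with
#' a stage-named message and removes partial outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the signal table, the logistic fit and the
#'   manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- file.path(config$out_dir,
                   c("signals.csv", "regression.csv", "manifest.json"))
  names(out) <- c("signals", "regression", "manifest")
  on_fail_cleanup <- function() unlink(out[file.exists(out)])

  res <- tryCatch({
    sets <- stage("config", load_term_config(config$term_config))
    rs <- stage("ingest", read_report_tables(
      config$demo, config$drug, config$adr,
      dictionary_paths = list(mp = config$mp, sun = config$sun,
                              atc = config$atc),
      options = config$options))
    if (!is.null(config$duplicates)) {
      dup <- stage("deduplicate",
                   read_duplicate_ids(config$duplicates, config$options))
      rs <- stage("deduplicate", exclude_duplicates(rs, dup))
    }
    rs <- stage("demographics", filter_known_demographics(rs))
    sig <- stage("signal", signal_table(rs, sets$drug_sets, sets$term_sets,
                                        config$priors,
                                        config$report_zero_n11))
    rsets <- config$regression_sets
    fit <- stage("regression", {
      design <- build_design(rs, sets$drug_sets[[rsets[["drug_set"]]]],
                             sets$term_sets[[rsets[["outcome"]]]],
                             sets$term_sets[[rsets[["covariate1"]]]],
                             sets$term_sets[[rsets[["covariate2"]]]])
      fit_logistic(design)
    })
    list(rs = rs, sig = sig, fit = fit)
  }, pvic_stage_error = function(e) { on_fail_cleanup(); stop(e) })

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sig_out <- copy(res$sig)
  for (col in c("e_ic", "v_ic", "ci_lower", "ci_upper"))
    sig_out[, (col) := fmt6(get(col))]
  sig_out[, ic_2dp := fmt2dp(res$sig$e_ic)]
  sig_out[, ci_2dp := ifelse(is.na(res$sig$e_ic), "NA",
                             sprintf("[%s to %s]", fmt2dp(res$sig$ci_lower),
                                     fmt2dp(res$sig$ci_upper)))]
  tmp <- paste0(out, ".tmp")
  fwrite(sig_out, tmp[1], na = "NA", quote = FALSE)
  fwrite(summarize_fit(res$fit), tmp[2], na = "NA", quote = FALSE)

  manifest <- list(
    package = "pvic",
    version = as.character(packageVersion("pvic")),
    config_hash = hash_config(config),
    inputs = input_checksums(config),
    provenance = as.data.frame(provenance(res$rs)),
    n_reports = n_reports(res$rs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, tmp[3], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  for (i in seq_along(out)) file.rename(tmp[i], out[i])
  invisible(list(signals = res$sig, fit = res$fit, manifest = manifest,
                 paths = out))
}

fmt2dp <- function(x) ifelse(is.na(x), "NA",
                             sprintf("%.2f", round_half_up(x, 2)))

hash_config <- function(config) {
  # content hash of everything that determines the outputs except the input
  # data themselves (those get per-file checksums)
  cfg <- config[c("term_config", "regression_sets", "report_zero_n11")]
  cfg$priors <- unclass(config$priors)
  cfg$options <- unclass(config$options)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

input_checksums <- function(config) {
  paths <- c(demo = config$demo, drug = config$drug, adr = config$adr,
             mp = config$mp, sun = config$sun)
  if (!is.null(config$atc)) paths["atc"] <- config$atc
  if (!is.null(config$duplicates)) paths["duplicates"] <- config$duplicates
  lapply(paths, function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
}
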