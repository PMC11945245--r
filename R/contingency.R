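#' Construct a contingency table from raw cell counts
#'
#' The four cells cross-classify case reports by exposure to a target drug
#' set (rows) and occurrence of a target event term set (columns): `n11`
#' exposed with event, `n10` exposed without, `n01` unexposed with event,
#' `n00` neither. Margins `n1p`, `np1` and the grand total `npp` are derived.
#'
#' @param n11,n10,n01,n00 non-negative integer counts.
#' @param drug_set,term_set optional set labels carried for display.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(n11, n10, n01, n00,
                              drug_set = NA_character_,
                              term_set = NA_character_) {
  for (v in list(n11, n10, n01, n00))
    if (!is_count(v))
      stop_pvic("contingency cells must be single non-negative integers",
                "pvic_invariant_error")
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 n1p = n11 + n10, np1 = n11 + n01,
                 npp = n11 + n10 + n01 + n00,
                 drug_set = drug_set, term_set = term_set),
            class = "contingency_table")
}

#' Build the contingency table for a drug set / term set pair
#'
#' Each report in the (already deduplicated, demographics-complete) report
#' set contributes to exactly one cell, classified at the patient level: a
#' report with several matching drug rows or event terms still counts once.
#' The comparator ("other drugs") is every report not exposed to this set,
#' including reports on other drugs of the same class.
#'
#' @param reports a `report_set`.
#' @param drug_set a [drug_set()].
#' @param term_set a [term_set()].
#' @return a [contingency_table()] whose `npp` equals `n_reports(reports)`.
#' @export
build_contingency <- function(reports, drug_set, term_set) {
  exposed <- resolve_exposure(reports, drug_set)
  event <- resolve_event(reports, term_set)
  contingency_table(n11 = sum(exposed & event),
                    n10 = sum(exposed & !event),
                    n01 = sum(!exposed & event),
                    n00 = sum(!exposed & !event),
                    drug_set = drug_set$name, term_set = term_set$name)
}

#' @export
print.contingency_table <- function(x, ...) {
  hdr <- if (!is.na(x$drug_set) || !is.na(x$term_set))
    sprintf(" [%s x %s]", x$drug_set, x$term_set) else ""
  cat(sprintf("<contingency_table>%s\n", hdr))
  m <- matrix(c(x$n11, x$n10, x$n1p,
                x$n01, x$n00, x$npp - x$n1p,
                x$np1, x$npp - x$np1, x$npp),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("target drugs", "other drugs", "total"),
                              c("target ADRs", "other ADRs", "total")))
  print(m)
  invisible(x)
}

#' @export
as.data.frame.contingency_table <- function(x, ...) {
  data.frame(drug_set = x$drug_set, term_set = x$term_set,
             n11 = x$n11, n10 = x$n10, n01 = x$n01, n00 = x$n00,
             n1p = x$n1p, np1 = x$np1, npp = x$npp,
             stringsAsFactors = FALSE)
}
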