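#' BCPNN prior constants
#'
#' Prior parameters of the Bayesian confidence propagation neural network
#' (BCPNN) information-component estimator in its closed form: a Dirichlet
#' prior on the joint cell (`gamma11`), Beta priors on the two margins
#' (`alpha1`, `beta1` the first shape parameters; `alpha`, `beta` the prior
#' sample sizes). The defaults are the standard choice
#' `gamma11 = alpha1 = beta1 = 1`, `alpha = beta = 2`, under which the prior
#' information component is centred at zero.
#'
#' @param gamma11,alpha1,beta1,alpha,beta strictly positive scalars.
#' @return an object of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(gamma11 = 1, alpha1 = 1, beta1 = 1,
                         alpha = 2, beta = 2) {
  vals <- c(gamma11 = gamma11, alpha1 = alpha1, beta1 = beta1,
            alpha = alpha, beta = beta)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop_pvic("all BCPNN priors must be strictly positive and finite",
              "pvic_config_error")
  structure(as.list(vals), class = "bcpnn_priors")
}

check_table <- function(table) {
  if (!inherits(table, "contingency_table"))
    stop_pvic("expected a contingency_table", "pvic_invariant_error")
  if (table$npp == 0)
    stop_pvic("information component is undefined for an empty table (npp = 0)",
              "pvic_invariant_error")
  table
}

# the dependent Dirichlet prior weight: gamma is tied to the margins so that
# the prior expectation of the IC is 0 for any table dimensions
ic_gamma <- function(table, priors) {
  with(c(table, priors),
       gamma11 * (npp + alpha) * (npp + beta) /
         ((n1p + alpha1) * (np1 + beta1)))
}

#' Expectation of the information component
#'
#' The information component (IC) is the posterior log2 ratio of the observed
#' to expected joint reporting probability of a drug set and an event term
#' set, under the BCPNN shrinkage priors. The closed form is
#' \deqn{E(IC) = \log_2 \frac{(n_{11}+\gamma_{11})(N+\alpha)(N+\beta)}
#'   {(N+\gamma)(n_{1+}+\alpha_1)(n_{+1}+\beta_1)}}
#' with \eqn{\gamma = \gamma_{11}(N+\alpha)(N+\beta) /
#'   ((n_{1+}+\alpha_1)(n_{+1}+\beta_1))}. Shrinkage keeps the value finite
#' for every valid table, including `n11 = 0`.
#'
#' @param table a [contingency_table()].
#' @param priors a [bcpnn_priors()] object.
#' @return E(IC) in bits (log2 units).
#' @export
ic_expectation <- function(table, priors = bcpnn_priors()) {
  check_table(table)
  g <- ic_gamma(table, priors)
  with(c(table, priors),
       log2((n11 + gamma11) * (npp + alpha) * (npp + beta) /
              ((npp + g) * (n1p + alpha1) * (np1 + beta1))))
}

#' Variance of the information component
#'
#' Closed-form posterior variance of the IC:
#' \deqn{V(IC) = \frac{1}{\ln^2 2}\left[
#'   \frac{N-n_{11}+\gamma-\gamma_{11}}{(n_{11}+\gamma_{11})(1+N+\gamma)} +
#'   \frac{N-n_{1+}+\alpha-\alpha_1}{(n_{1+}+\alpha_1)(1+N+\alpha)} +
#'   \frac{N-n_{+1}+\beta-\beta_1}{(n_{+1}+\beta_1)(1+N+\beta)} \right]}
#' Strictly positive and finite for every valid table.
#'
#' @inheritParams ic_expectation
#' @return V(IC) in bits squared.
#' @export
ic_variance <- function(table, priors = bcpnn_priors()) {
  check_table(table)
  g <- ic_gamma(table, priors)
  with(c(table, priors),
       (1 / log(2)^2) *
         ((npp - n11 + g - gamma11) / ((n11 + gamma11) * (1 + npp + g)) +
          (npp - n1p + alpha - alpha1) / ((n1p + alpha1) * (1 + npp + alpha)) +
          (npp - np1 + beta - beta1) / ((np1 + beta1) * (1 + npp + beta))))
}

#' 95\% credibility interval of the information component
#'
#' The interval is \eqn{E(IC) \pm 2\sqrt{V(IC)}} — the conventional
#' two-standard-deviation band used with this estimator (the multiplier is
#' exactly 2, not 1.96).
#'
#' @inheritParams ic_expectation
#' @return named numeric vector `c(ci_lower, ci_upper)` in bits.
#' @export
ic_interval <- function(table, priors = bcpnn_priors()) {
  e <- ic_expectation(table, priors)
  half <- 2 * sqrt(ic_variance(table, priors))
  c(ci_lower = e - half, ci_upper = e + half)
}

#' Full IC analysis of one contingency table
#'
#' @inheritParams ic_expectation
#' @return an `ic_result`: `e_ic`, `v_ic`, `ci_lower`, `ci_upper` (bits) and
#'   the tri-state `signal` verdict (see [classify_signal()]).
#' @export
ic_analysis <- function(table, priors = bcpnn_priors()) {
  e <- ic_expectation(table, priors)
  v <- ic_variance(table, priors)
  half <- 2 * sqrt(v)
  res <- structure(list(e_ic = e, v_ic = v,
                        ci_lower = e - half, ci_upper = e + half,
                        signal = NA_character_),
                   class = "ic_result")
  res$signal <- classify_signal(table, res)
  res
}

#' Tri-state signal verdict
#'
#' A drug–event pair is a signal (`"YES"`) when the lower limit of the IC's
#' 95\% credibility interval exceeds 0. Pairs with no co-reported case
#' (`n11 = 0`) are reported `"NA"` — the IC is still computable under
#' shrinkage, but a pair never reported together is conventionally not
#' classified. Everything else is `"NO"`.
#'
#' @param table a [contingency_table()].
#' @param ic an `ic_result` (or any list with `ci_lower`).
#' @return one of `"YES"`, `"NO"`, `"NA"`.
#' @export
classify_signal <- function(table, ic) {
  if (table$n11 == 0) return("NA")
  if (ic$ci_lower > 0) "YES" else "NO"
}

#' @export
print.ic_result <- function(x, ...) {
  cat(sprintf("<ic_result> IC = %.2f [%.2f to %.2f], signal: %s\n",
              round_half_up(x$e_ic, 2), round_half_up(x$ci_lower, 2),
              round_half_up(x$ci_upper, 2), x$signal))
  invisible(x)
}

#' Signal screen over all drug set / term set pairs
#'
#' Builds the contingency table and IC analysis for every pair, in the config
#' order of the supplied sets. For pairs with `n11 = 0` the numeric IC
#' columns are masked to `NA` (matching the conventional reporting of such
#' rows) unless `report_zero_n11 = TRUE`, which emits the computed values
#' while keeping the `"NA"` verdict.
#'
#' @param reports a filtered `report_set`.
#' @param drug_sets,term_sets named lists of [drug_set()] / [term_set()]
#'   objects (see [load_term_config()]).
#' @param priors a [bcpnn_priors()] object.
#' @param report_zero_n11 emit computed IC values for `n11 = 0` rows?
#' @return data.table with one row per pair: set names, the four cells,
#'   `e_ic`, `v_ic`, `ci_lower`, `ci_upper` and `signal`.
#' @export
signal_table <- function(reports, drug_sets, term_sets,
                         priors = bcpnn_priors(), report_zero_n11 = FALSE) {
  rows <- list()
  expo <- lapply(drug_sets, function(d) unname(resolve_exposure(reports, d)))
  evt <- lapply(term_sets, function(t) unname(resolve_event(reports, t)))
  for (di in seq_along(drug_sets)) for (ti in seq_along(term_sets)) {
    d <- drug_sets[[di]]; t <- term_sets[[ti]]
    ex <- expo[[di]]; ev <- evt[[ti]]
    tab <- contingency_table(sum(ex & ev), sum(ex & !ev),
                             sum(!ex & ev), sum(!ex & !ev),
                             drug_set = d$name, term_set = t$name)
    ic <- ic_analysis(tab, priors)
    mask <- tab$n11 == 0 && !report_zero_n11
    rows[[length(rows) + 1L]] <- data.table(
      drug_set = d$name, term_set = t$name,
      n11 = tab$n11, n10 = tab$n10, n01 = tab$n01, n00 = tab$n00,
      e_ic = if (mask) NA_real_ else ic$e_ic,
      v_ic = if (mask) NA_real_ else ic$v_ic,
      ci_lower = if (mask) NA_real_ else ic$ci_lower,
      ci_upper = if (mask) NA_real_ else ic$ci_upper,
      signal = ic$signal)
  }
  if (length(rows) == 0)
    return(data.table(drug_set = character(), term_set = character(),
                      n11 = integer(), n10 = integer(), n01 = integer(),
                      n00 = integer(), e_ic = numeric(), v_ic = numeric(),
                      ci_lower = numeric(), ci_upper = numeric(),
                      signal = character()))
  rbindlist(rows)
}
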