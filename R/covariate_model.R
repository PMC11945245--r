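#' Build the covariate design for the fracture regression
#'
#' Restricts to reports exposed to the target drug set and derives one row
#' per report: the fracture outcome and four binary covariates — age 65 or
#' over, female sex, osteoporosis reported, hyperthyroidism reported.
#' Reference levels are under-65, male, and condition absent. The report set
#' is expected to be demographics-complete, so no covariate is missing.
#'
#' @param reports a filtered `report_set`.
#' @param icis [drug_set()] defining the exposed population.
#' @param fracture_set,osteo_set,hyper_set [term_set()]s defining the outcome
#'   and the two comorbidity covariates.
#' @return data.table with columns `report_id`, `outcome`, `age65`, `female`,
#'   `osteoporosis`, `hyperthyroidism` (logical), one row per exposed report.
#' @export
build_design <- function(reports, icis, fracture_set, osteo_set, hyper_set) {
  stopifnot(inherits(reports, "report_set"))
  exposed <- resolve_exposure(reports, icis)
  if (!any(exposed))
    stop_pvic(sprintf("no report is exposed to drug set '%s'; design is empty",
                      icis$name), "pvic_invariant_error")
  keep <- which(exposed)
  demo <- reports$demo[keep]
  data.table(
    report_id = demo$report_id,
    outcome = unname(resolve_event(reports, fracture_set))[keep],
    age65 = demo$age_years >= 65,
    female = demo$sex == "female",
    osteoporosis = unname(resolve_event(reports, osteo_set))[keep],
    hyperthyroidism = unname(resolve_event(reports, hyper_set))[keep])
}

logistic_deviance <- function(y, mu) {
  -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression of `outcome` on every other
#' non-identifier column of the design (coerced to 0/1), with an intercept.
#' Convergence is declared when the largest absolute coefficient change
#' drops below `tol` (default 1e-8), up to `max_iter` iterations. Wald 95\%
#' intervals (multiplier 1.96) and two-sided Wald p-values are attached.
#' Complete or quasi-separation is flagged — not corrected — when any
#' coefficient magnitude diverges past 15 on the logit scale.
#'
#' @param rows design table with a logical/0-1 `outcome` column and one
#'   column per covariate (`report_id`, if present, is ignored).
#' @param tol convergence tolerance on the coefficient step.
#' @param max_iter iteration cap.
#' @return a `logistic_fit`: named `coefficients`, `se`, `odds_ratio`,
#'   `ci_lower`, `ci_upper`, `p_value`, the `convergence` status
#'   (`"converged"`, `"max_iter"` or `"separated"`), the per-iteration
#'   `deviance_trace`, and `n`.
#' @export
fit_logistic <- function(rows, tol = 1e-8, max_iter = 100L) {
  rows <- as.data.frame(rows)
  if (!"outcome" %in% names(rows))
    stop_pvic("design must contain an 'outcome' column", "pvic_invariant_error")
  y <- as.numeric(rows$outcome)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_pvic("outcome must be binary with no missing values",
              "pvic_invariant_error")
  if (length(unique(y)) < 2)
    stop_pvic("outcome has a single class; logistic model cannot be fit",
              "pvic_invariant_error")
  covs <- setdiff(names(rows), c("outcome", "report_id"))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(lapply(rows[covs], as.numeric))))
  if (anyNA(X))
    stop_pvic("covariates must be numeric/logical with no missing values",
              "pvic_invariant_error")
  const <- covs[apply(X[, -1, drop = FALSE], 2, function(v) length(unique(v)) < 2)]
  if (length(const))
    stop_pvic(sprintf("covariate(s) constant in the design, model not identifiable: %s",
                      paste(const, collapse = ", ")), "pvic_identifiability_error")
  p <- ncol(X)
  beta <- numeric(p)
  dev_trace <- numeric(0)
  status <- "max_iter"
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), .Machine$double.eps)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    fit <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(fit))
      stop_pvic("weighted least-squares system is singular; covariates are collinear",
                "pvic_identifiability_error")
    new_beta <- drop(fit)
    dev_trace <- c(dev_trace, logistic_deviance(y, plogis(drop(X %*% new_beta))))
    step <- max(abs(new_beta - beta))
    beta <- new_beta
    if (any(abs(beta) > 15)) { status <- "separated"; break }
    if (step < tol) { status <- "converged"; break }
  }
  if (status == "separated")
    warning("possible complete/quasi-separation: a coefficient exceeded 15 on the logit scale; estimates are unreliable")
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  cov_beta <- solve(t(X * w) %*% X)
  se <- sqrt(diag(cov_beta))
  zstat <- beta / se
  names(beta) <- names(se) <- colnames(X)
  structure(list(
    coefficients = beta,
    se = se,
    odds_ratio = exp(beta),
    ci_lower = exp(beta - qnorm(0.975) * se),
    ci_upper = exp(beta + qnorm(0.975) * se),
    p_value = 2 * pnorm(-abs(zstat)),
    convergence = status,
    iterations = it,
    deviance = dev_trace[length(dev_trace)],
    deviance_trace = dev_trace,
    loglik = -dev_trace[length(dev_trace)] / 2,
    n = length(y)), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, %s in %d iteration(s), deviance %.3f\n",
              x$n, x$convergence, x$iterations, x$deviance))
  print(summarize_fit(x), row.names = FALSE)
  invisible(x)
}

#' Tidy summary of a logistic fit
#'
#' One row per covariate (the intercept is omitted, as in standard clinical
#' reporting tables) with the odds ratio, Wald 95\% interval and p-value,
#' plus display columns rounded to 2 decimals ("<0.001" for small p).
#'
#' @param fit a `logistic_fit`.
#' @return data.frame with columns `term`, `odds_ratio`, `ci_lower`,
#'   `ci_upper`, `p_value`, `or_95ci` (formatted) and `p` (formatted).
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  keep <- setdiff(names(fit$coefficients), "(Intercept)")
  data.frame(
    term = keep,
    odds_ratio = fit$odds_ratio[keep],
    ci_lower = fit$ci_lower[keep],
    ci_upper = fit$ci_upper[keep],
    p_value = fit$p_value[keep],
    or_95ci = sprintf("%.2f [%.2f-%.2f]",
                      round_half_up(fit$odds_ratio[keep], 2),
                      round_half_up(fit$ci_lower[keep], 2),
                      round_half_up(fit$ci_upper[keep], 2)),
    p = format_p(fit$p_value[keep]),
    row.names = NULL, stringsAsFactors = FALSE)
}
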