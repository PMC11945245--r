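test_that("design rows cover exactly the exposed reports with set-derived flags", {
  coh <- generate_cohort_for_regression(5000, seed = 41)
  sets <- load_term_config()
  rs <- filter_known_demographics(report_set_from_tables(coh$tables))
  d <- build_design(rs, sets$drug_sets$all_icis, sets$term_sets$fractures,
                    sets$term_sets$osteoporosis, sets$term_sets$hyperthyroidism)
  expect_equal(nrow(d), 5000L)
  truth <- coh$truth$flags
  setkey(truth, report_id); setkeyv(d, "report_id")
  expect_equal(d$outcome, truth$outcome)
  expect_equal(d$age65, truth$age65)
  expect_equal(d$female, truth$female)
  expect_equal(d$osteoporosis, truth$osteoporosis)
  expect_equal(d$hyperthyroidism, truth$hyperthyroidism)
})

test_that("unexposed reports are excluded; an all-unexposed set errors", {
  demo <- data.frame(report_id = c("A", "B"), age = c(70, 50),
                     sex = c("female", "male"))
  drug <- data.frame(report_id = c("A", "B"),
                     substance_id = c(27193L, 55555L))
  rs <- rs_from(demo, drug)
  sets <- load_term_config()
  d <- build_design(rs, sets$drug_sets$all_icis, sets$term_sets$fractures,
                    sets$term_sets$osteoporosis, sets$term_sets$hyperthyroidism)
  expect_equal(d$report_id, "A")
  expect_equal(d$age65, TRUE)
  expect_error(
    build_design(rs, sets$drug_sets$tremelimumab, sets$term_sets$fractures,
                 sets$term_sets$osteoporosis, sets$term_sets$hyperthyroidism),
    "tremelimumab", class = "pvic_invariant_error")
})

test_that("single binary covariate reproduces the closed-form odds ratio", {
  rows <- data.frame(
    outcome = rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 60, 20, 80)),
    exposed = rep(c(TRUE, TRUE, FALSE, FALSE), c(40, 60, 20, 80)))
  fit <- fit_logistic(rows)
  expect_equal(unname(fit$odds_ratio["exposed"]), (40 * 80) / (60 * 20),
               tolerance = 1e-6)
  expect_equal(fit$convergence, "converged")
})

test_that("coefficients, errors and p-values match the reference glm fit", {
  coh <- generate_cohort_for_regression(20000, seed = 7)
  sets <- load_term_config()
  rs <- filter_known_demographics(report_set_from_tables(coh$tables))
  d <- build_design(rs, sets$drug_sets$all_icis, sets$term_sets$fractures,
                    sets$term_sets$osteoporosis, sets$term_sets$hyperthyroidism)
  fit <- fit_logistic(d)
  g <- stats::glm(outcome ~ age65 + female + osteoporosis + hyperthyroidism,
                  data = d, family = stats::binomial(),
                  control = stats::glm.control(epsilon = 1e-12))
  gcoef <- stats::coef(g)
  names(gcoef) <- sub("TRUE$", "", names(gcoef))
  expect_equal(fit$coefficients, gcoef, tolerance = 1e-6)
  gse <- sqrt(diag(stats::vcov(g)))
  names(gse) <- sub("TRUE$", "", names(gse))
  expect_equal(fit$se, gse, tolerance = 1e-6)
  expect_equal(unname(fit$ci_lower),
               unname(exp(gcoef - stats::qnorm(0.975) * gse)), tolerance = 1e-6)
})

test_that("deviance never increases across IRLS iterations", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 500
    d <- data.frame(outcome = runif(n) < 0.3,
                    x1 = runif(n) < 0.5, x2 = runif(n) < 0.4)
    fit <- fit_logistic(d)
    expect_true(all(diff(fit$deviance_trace) <= 1e-8))
  }
})

test_that("row order does not change any reported value", {
  coh <- generate_cohort_for_regression(3000, seed = 13)
  sets <- load_term_config()
  rs <- filter_known_demographics(report_set_from_tables(coh$tables))
  d <- build_design(rs, sets$drug_sets$all_icis, sets$term_sets$fractures,
                    sets$term_sets$osteoporosis, sets$term_sets$hyperthyroidism)
  f1 <- fit_logistic(d)
  set.seed(1)
  f2 <- fit_logistic(d[sample(nrow(d)), ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-10)
})

test_that("separation is flagged, single-class and constant columns error", {
  sep <- data.frame(outcome = rep(c(TRUE, FALSE), each = 50),
                    x = rep(c(TRUE, FALSE), each = 50))
  expect_warning(fit <- fit_logistic(sep), "separation")
  expect_equal(fit$convergence, "separated")
  expect_error(fit_logistic(data.frame(outcome = rep(TRUE, 10),
                                       x = runif(10) < 0.5)),
               "single class", class = "pvic_invariant_error")
  expect_error(fit_logistic(data.frame(outcome = runif(50) < 0.5,
                                       x = rep(TRUE, 50))),
               "constant", class = "pvic_identifiability_error")
})

test_that("fit summaries are formatted like clinical reporting tables", {
  coh <- generate_cohort_for_regression(8000, seed = 3)
  sets <- load_term_config()
  rs <- filter_known_demographics(report_set_from_tables(coh$tables))
  d <- build_design(rs, sets$drug_sets$all_icis, sets$term_sets$fractures,
                    sets$term_sets$osteoporosis, sets$term_sets$hyperthyroidism)
  s <- summarize_fit(fit_logistic(d))
  expect_equal(s$term, c("age65", "female", "osteoporosis", "hyperthyroidism"))
  expect_false("(Intercept)" %in% s$term)
  # formatting rules, checked via the package-level helpers on known values
  expect_equal(pvic:::format_p(0.0004), "<0.001")
  expect_equal(pvic:::format_p(0.377), "0.377")
  expect_equal(round_half_up(2.6667, 2), 2.67)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_match(s$or_95ci[1], "^\\d+\\.\\d{2} \\[\\d+\\.\\d{2}-\\d+\\.\\d{2}\\]$")
})

test_that("coefficient bias shrinks as the cohort grows", {
  truth <- c(`(Intercept)` = -4, age65 = 0.5, female = 0.45,
             osteoporosis = 2, hyperthyroidism = 0)
  mae <- vapply(c(5000, 50000, 200000), function(n) {
    errs <- vapply(1:5, function(s) {
      coh <- generate_cohort_for_regression(n, truth = truth, seed = 600 + s)
      est <- fit_logistic(coh$truth$flags)$coefficients[names(truth)]
      mean(abs(est - truth))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mae) < 0), label = paste(signif(mae, 3), collapse = " > "))
  expect_lt(mae[3], 0.05)
})
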