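---
title: "Methods: BCPNN disproportionality analysis in pvic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BCPNN disproportionality analysis in pvic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and data model

`pvic` analyses spontaneous adverse-event reports organised the way the WHO
global pharmacovigilance database distributes them: a DEMO table with one
row per case report (age, sex), DRUG and ADR detail tables keyed by
`report_id`, dictionary tables (MP, SUN, ATC) that resolve drug rows to
substance ids and ATC codes, and a SUSPECTEDDUPLICATES list produced
upstream by the database provider's statistical duplicate-detection
algorithm. One retained case report is treated as one patient throughout;
no cross-report patient linkage is attempted, because the published
screening convention counts patients as reports and the margins of the
screens this package reproduces sum accordingly.

The analysis population is constructed in two filter steps after ingest:
suspected duplicates are excluded, then reports with unknown age or sex are
dropped. Both filters are pure row predicates, so they commute and are
idempotent — properties the test suite asserts — and every step appends a
provenance row (`n_in`, `n_removed`, `n_out`) that must reconcile exactly.

Duplicate detection itself is *not* implemented: the duplicate list is an
input. Re-deriving a probabilistic record-linkage algorithm is a separate
research problem, and treating the list as data keeps the pipeline's
behaviour fully determined by its inputs.

## Exposure and event mapping

Exposure and event status are set memberships: a report is exposed to a
drug set if any of its drug rows carries one of the set's substance ids,
and has an event if any ADR row carries one of the term set's
preferred-term codes. Multiple matching rows count once — classification is
at the patient level. Two consequences worth making explicit:

- The comparator for a single-agent set is "this drug not reported", which
  includes patients on the other drugs of the same class. This matches the
  margin arithmetic of the published screens (each agent's event margin
  `n+1` equals the whole-population margin).
- No distinction is made between suspected and concomitant drug roles; all
  drug rows confer exposure. The source extracts do not always carry the
  role flag, and the published margins cannot distinguish the two
  conventions. Restricting to suspected drugs is a config-level extension
  point, not a code change.

Term sets are flat preferred-term lists. Standardised-query scope logic and
term-hierarchy traversal are out of scope by design; the `grouping_source`
field on a term set is provenance only. The packaged config ships the six
checkpoint-inhibitor substance ids (tremelimumab has two) and *fixture*
preferred-term code lists with the documented cardinalities — 11
osteoporosis terms, 19 hyperthyroidism terms, 78 fracture terms in six
high-level-term blocks — drawn from a reserved 90000xxx range, because real
dictionary codes are licensed. Users substitute their licensed lists via
the same YAML schema.

Unknown demographics may be encoded as empty fields, `"NA"`, or
site-specific sentinel codes; `reader_options()` controls this, and an
optional code-to-midpoint map supports age given as group codes. Midpoints
suffice because the only downstream use of age is the 65-year dichotomy.

## The information component

For each (drug set, term set) pair the population is cross-classified into
`n11, n10, n01, n00` with margins `n1+`, `n+1`, `N`. The BCPNN information
component is the posterior log2 ratio of observed to expected joint
reporting probability under dependent Dirichlet/Beta shrinkage priors with
the standard constants `γ11 = 1`, `α1 = β1 = 1`, `α = β = 2` (overridable
via `bcpnn_priors()`; all must be strictly positive). The closed forms for
`E(IC)` and `V(IC)` are given in the README and implemented in
`ic_expectation()` / `ic_variance()`; the joint prior weight γ is tied to
the margins so that the prior IC is centred at zero for any table shape.

Numerical behaviour the implementation guarantees, and the tests check:

- finite values for every valid table, including `n11 = 0` (no infinities
  anywhere);
- strict monotonicity of `E(IC)` in `n11` with the other cells fixed;
- convergence to the maximum-likelihood IC `log2(n11·N/(n1+·n+1))` as a
  fixed-ratio table scales up;
- agreement with an independently transcribed implementation of the two
  formulas to 1e-12 bits over 1,000 random tables spanning small and large
  count regimes.

The credibility interval is `E(IC) ± 2√V(IC)`; the multiplier is exactly 2,
the convention used with this estimator, not a Gaussian 1.96. The signal
rule is tri-state: `YES` when the lower bound exceeds 0, `NA` when
`n11 = 0` (a never-co-reported pair is conventionally not classified, even
though the shrunk IC is computable — `report_zero_n11 = TRUE` emits the
computed value while keeping the `NA` verdict), `NO` otherwise.

Display rounding is half-away-from-zero to 2 decimals (`round_half_up()`),
matching how such screens are printed; internal values keep full precision,
and the pipeline's CSV output carries both 6-significant-digit and 2-decimal
columns. One caveat learned from validating against published tables:
independently computed interval bounds can disagree with printed ones in
the last digit when the upstream software rounded from a slightly different
intermediate, and isolated typographical errors (a sign, a transposed
digit) do occur; validation should always cross-check a printed interval
against its own midpoint.

## The covariate model

Among reports exposed to the target drug set, event reporting is modelled
by logistic regression on four binary covariates: age ≥ 65 (reference
under 65), female (reference male), osteoporosis reported, hyperthyroidism
reported. The fit is plain maximum likelihood via IRLS, initialised at zero
coefficients, converged when the largest absolute coefficient step falls
below 1e-8 (cap 100 iterations). Intervals are Wald with multiplier 1.96 —
the default of the GUI statistics environments these analyses are typically
run in — and p-values are two-sided Wald. Deliberate choices:

- No rare-event (Firth) correction: the reference workflow used plain
  logistic regression. Complete or quasi-separation is therefore a real
  risk with rare covariates; it is *detected* (any coefficient magnitude
  passing 15 on the logit scale) and flagged with a warning, never
  silently corrected.
- A covariate constant in the design (for example a zero-prevalence
  comorbidity) raises an explicit non-identifiability error rather than
  returning an arbitrary coefficient.
- No interaction terms or continuous age: the model is exactly the four
  binary covariates.

The hand-rolled IRLS exists so that the convergence contract, the deviance
trace (asserted non-increasing) and the separation flag are fully under the
package's control; `stats::glm` serves as an independent cross-check oracle
in the tests (agreement to 1e-6 on coefficients and standard errors), never
as the implementation.

## The synthetic-data generator

The generator emulates the relational structure with planted truth so that
every stage is testable without the access-restricted source database.

Per clean report it draws demographics (ages uniform 18–95, sexes
balanced), independent per-drug-set exposures, and per-term-set events with
probability `λ(S,T) · background(T)` given exposure (products over
multiply-exposed reports, clipped to 1). Filler drug rows and background
ADR terms are added so tables have realistic non-target content. Duplicates
are literal copies of sampled clean reports under fresh ids, listed in
SUSPECTEDDUPLICATES; unknown demographics blank age, sex or both. A truth
record carries the clean count, the demographics-known count and the exact
contingency cells of every pair over the post-filter population, which the
tests reconcile cell-for-cell against the pipeline.

Default condition choices, made once: duplicate contamination 5% and
unknown-demographics rate 12% (the planted rates the filters are validated
against); per-agent exposure 0.02 and background event rates 0.004 /
0.003 / 0.012 (osteoporosis / hyperthyroidism / fractures). The background
rates preserve the relative ADR frequencies of the motivating screen
(roughly 37k : 14k : 104k per 26M) at a benchmark scale where expected
co-reporting counts at n = 50,000 are of order 3–12 — large enough for
signal-detection behaviour to be observable, small enough for fast tests.
The multiplicative association model was chosen because it makes
`log2(λ)` the IC's large-sample target, giving closed-form expectations
for calibration tests.

What the generator does *not* emulate: reporting dates and secular trends,
country and reporter fields, narrative text, drug-role flags, correlated
multi-drug regimens, and realistic duplicate structure (true duplicates in
the wild are near-copies with discrepancies; here they are exact copies,
which is sufficient because the pipeline consumes a supplied duplicate
list rather than detecting duplicates). Passing tests therefore validate
the pipeline's arithmetic and contracts, not the epidemiological fidelity
of any real database.

`plant_exact()` complements the stochastic generator: it emits a dataset
that yields an exactly requested contingency table after the standard
ingest-and-filter path, using run-length construction (each cell a
contiguous block). It plants one pair per dataset — sufficient for
validation, since jointly planting all screens of a published table
requires a joint distribution the published margins do not determine.
`scale_divisor` shrinks cells with exact integer arithmetic and refuses
non-divisible cells. Paper-scale (26-million-row) planting is supported but
slow; the shipped tests validate end-to-end exactness on divisor-scaled
replicas of every published row plus a well-conditioned large-sample
consistency check, because proportionally scaled-down versions of the
published rows have expected counts below 1, where the shrinkage prior
dominates and the maximum-likelihood limit is not informative.

## Problem sizes used in the shipped tests

Chosen to exercise each property at the smallest scale where it is
meaningful: brute-force contingency oracles at 200 reports; generator
reconciliation at 3,000–10,000; null signal calibration over 200 seeds at
50,000 reports per seed; planted-association recovery at 100,000;
regression parameter recovery over 50 seeds at 200,000 (recovering, among
others, an odds ratio of 118 on a 2%-prevalence covariate); null
regression calibration over 200 replicates at 20,000. End-to-end planted
replicas use scale divisor 500 (populations of ~52,000).

## Known limitations

- Only the IC estimator is implemented; reporting odds ratio, PRR and
  empirical-Bayes alternatives are extension points.
- Flat term lists only; no hierarchy or scope logic.
- The regression population is "all reports exposed to the drug set after
  filtering"; if a study restricts further (for example by date window),
  that restriction must be applied upstream.
- Wald inference is poor near separation; the package flags it and leaves
  remediation (exact logistic, Firth) to the analyst.
- Disproportionality measures reporting association, not incidence or
  causation; all the biases of passive reporting (under- and over-
  reporting, confounding by indication and comorbidity) pass through
  arithmetic untouched.
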