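# Independent literal transcription of the closed-form IC expectation and
# variance, written directly from the published equations with no code
# shared with the package implementation. Used only as a cross-check oracle.

oracle_e_ic <- function(n11, n10, n01, n00,
                        gamma11 = 1, alpha1 = 1, beta1 = 1,
                        alpha = 2, beta = 2) {
  Npp <- n11 + n10 + n01 + n00
  N1p <- n11 + n10
  Np1 <- n11 + n01
  gamma <- gamma11 * (Npp + alpha) * (Npp + beta) /
    ((N1p + alpha1) * (Np1 + beta1))
  log((n11 + gamma11) * (Npp + alpha) * (Npp + beta) /
        ((Npp + gamma) * (N1p + alpha1) * (Np1 + beta1))) / log(2)
}

oracle_v_ic <- function(n11, n10, n01, n00,
                        gamma11 = 1, alpha1 = 1, beta1 = 1,
                        alpha = 2, beta = 2) {
  Npp <- n11 + n10 + n01 + n00
  N1p <- n11 + n10
  Np1 <- n11 + n01
  gamma <- gamma11 * (Npp + alpha) * (Npp + beta) /
    ((N1p + alpha1) * (Np1 + beta1))
  (1 / (log(2))^2) * (
    (Npp - n11 + gamma - gamma11) / ((n11 + gamma11) * (1 + Npp + gamma)) +
    (Npp - N1p + alpha - alpha1) / ((N1p + alpha1) * (1 + Npp + alpha)) +
    (Npp - Np1 + beta  - beta1)  / ((Np1 + beta1)  * (1 + Npp + beta)))
}

# random contingency tables spanning small and large regimes
random_cells <- function(n_tables, seed) {
  set.seed(seed)
  data.frame(
    n11 = rpois(n_tables, lambda = sample(c(0.5, 2, 20, 300), n_tables,
                                          replace = TRUE)),
    n10 = rpois(n_tables, lambda = sample(c(5, 100, 5000), n_tables,
                                          replace = TRUE)),
    n01 = rpois(n_tables, lambda = sample(c(5, 100, 5000), n_tables,
                                          replace = TRUE)),
    n00 = rpois(n_tables, lambda = sample(c(100, 1e4, 1e6), n_tables,
                                          replace = TRUE)))
}
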