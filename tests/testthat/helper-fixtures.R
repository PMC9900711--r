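## shared fixtures built in code

fig2_epi <- function(amp = 0.5) {
  epi_params(a0 = 10, q0 = 0.5, b = 1, alpha = 1, gamma = 1, beta = 0.2,
             amp = amp)
}

fig2_tradeoff <- function(tau2 = -3) {
  tradeoff_params(a_ref = 10, beta_ref = 0.2, tau1 = 1.58, tau2 = tau2)
}

fig4_epi <- function() {
  epi_params(a0 = 10, q0 = 0.1, b = 1, alpha = 1, gamma = 0.1, beta = 0.1,
             theta = 5, decay = 0.1)
}

fig4_tradeoff <- function() {
  tradeoff_params(a_ref = 10, beta_ref = 0.1, tau1 = 75, tau2 = -400)
}

## endemic equilibrium computed independently in-test (selection-gradient
## oracles build their own Jacobians from this, not from package internals)
endemic_eq <- function(p, a) {
  k <- p$b + p$alpha + p$gamma
  S <- k / p$beta
  I <- (a - p$q0 * S - p$b) * S / ((p$q0 + p$beta) * S - p$gamma)
  c(S = S, I = I)
}

## dominant eigenvalue of the 2x2 mutant Jacobian at the endemic
## equilibrium, assembled directly from the model coefficients
eigen_fitness_oracle <- function(p, tr, beta_m, beta_r) {
  p$beta <- beta_r
  a_r <- if (is.null(tr)) p$a0 else birth_rate(tr, beta_r)
  a_m <- if (is.null(tr)) p$a0 else birth_rate(tr, beta_m)
  eq <- endemic_eq(p, a_r)
  k <- p$b + p$alpha + p$gamma
  J <- matrix(c(a_m - p$q0 * sum(eq) - p$b - beta_m * eq[["I"]], p$gamma,
                beta_m * eq[["I"]], -k), 2, 2, byrow = TRUE)
  max(Re(eigen(J, only.values = TRUE)$values))
}
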