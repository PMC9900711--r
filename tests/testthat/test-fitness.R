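test_that("a strain invading itself is neutral on every preset", {
  cases <- list(
    list(v = "seasonal", p = fig2_epi(0.5), tr = NULL, beta = 0.2),
    list(v = "seasonal", p = fig2_epi(0.5), tr = fig2_tradeoff(-3), beta = 0.25),
    list(v = "seasonal", p = fig2_epi(0.5), tr = fig2_tradeoff(3), beta = 0.25),
    list(v = "free_living", p = fig4_epi(), tr = NULL, beta = 0.1),
    list(v = "free_living", p = fig4_epi(), tr = fig4_tradeoff(), beta = 0.1))
  for (cs in cases) {
    s <- invasion_fitness(cs$v, cs$p, cs$tr, cs$beta, cs$beta)
    expect_lt(abs(s$value), 1e-4)
  }
})

test_that("mutant derivatives are linear and decouple without recovery", {
  p <- fig2_epi(amp = 0)
  tr <- fig2_tradeoff()
  res <- c(15, 22.5 / 9.5)
  expect_identical(mutant_rhs("baseline", p, tr, 0.25, 0, c(0, 0), res),
                   c(0, 0))
  ## linearity in the mutant state
  m <- c(0.3, 0.7)
  expect_equal(mutant_rhs("baseline", p, tr, 0.25, 0, 2 * m, res),
               2 * mutant_rhs("baseline", p, tr, 0.25, 0, m, res))
  ## gamma = 0: the S_m equation is the bare growth form, term by term
  p0 <- p; p0$gamma <- 0
  d <- mutant_rhs("baseline", p0, tr, 0.25, 0, c(1, 0), res)
  expect_equal(d[1],
               birth_rate(tr, 0.25) - p0$q0 * sum(res) - p0$b - 0.25 * res[2])
  expect_equal(d[2], 0.25 * res[2])
})

test_that("monodromy on an equilibrium equals the matrix exponential", {
  skip_if_not_installed("Matrix")
  p <- fig2_epi(amp = 0)
  tr <- fig2_tradeoff()
  p$beta <- 0.25
  att <- resident_attractor("baseline", p, tr)
  expect_identical(att$kind, "equilibrium")
  mono <- monodromy_matrix(att, 0.3)
  ## independent oracle: C = expm(J T) with J assembled from the model
  a_m <- birth_rate(tr, 0.3)
  eq <- att$phase0_state
  k <- p$b + p$alpha + p$gamma
  J <- matrix(c(a_m - p$q0 * (eq[1] + eq[2]) - p$b - 0.3 * eq[2], p$gamma,
                0.3 * eq[2], -k), 2, 2, byrow = TRUE)
  C_oracle <- as.matrix(Matrix::expm(J * att$period))
  expect_equal(unname(mono$C), unname(C_oracle), tolerance = 1e-6)
  expect_equal(mono$exponent, max(Re(eigen(J)$values)), tolerance = 1e-7)
})

test_that("multipliers are invariant to the mutant basis and cycle phase", {
  p <- fig2_epi(amp = 0.5)
  p$beta <- 0.25
  att <- resident_attractor("seasonal", p, fig2_tradeoff())
  m0 <- monodromy_matrix(att, 0.28)
  m1 <- monodromy_matrix(att, 0.28,
                         init = matrix(c(1, 0.3, 1, -0.7), 2, 2))
  expect_lt(max(abs(sort(Mod(m0$multipliers)) -
                      sort(Mod(m1$multipliers)))), 1e-8)
  for (idx in c(51L, 101L, 151L)) {
    mp <- monodromy_matrix(att, 0.28, start_index = idx)
    expect_lt(abs(mp$exponent - m0$exponent), 1e-6)
  }
  expect_error(monodromy_matrix(att, 0.28, init = matrix(1, 2, 2)),
               "non-singular")
})

test_that("without recovery the Floquet exponent is the period-averaged growth", {
  p <- epi_params(a0 = 10, q0 = 0.5, b = 1, alpha = 1, gamma = 0,
                  beta = 0.2, amp = 0.5)
  tr <- fig2_tradeoff()
  att <- resident_attractor("seasonal", p, tr)
  expect_identical(att$kind, "cycle")
  for (bm in c(0.15, 0.2, 0.3)) {
    fl <- monodromy_matrix(att, bm)$exponent
    av <- average_growth_fitness(p, tr, bm, att)
    expect_lt(abs(fl - av), 1e-5)
  }
  ## neutrality of the averaged form
  expect_lt(abs(average_growth_fitness(p, tr, 0.2, att)), 1e-6)
  ## structured mutants are rejected
  p1 <- p; p1$gamma <- 1
  expect_error(average_growth_fitness(p1, tr, 0.2, att), "gamma")
})

test_that("constant coefficients reduce the averaged growth to the simple form", {
  p <- epi_params(a0 = 10, q0 = 0.5, b = 1, alpha = 1, gamma = 0,
                  beta = 0.2, amp = 0)
  tr <- fig2_tradeoff()
  att <- resident_attractor("baseline", p, tr)
  expect_identical(att$kind, "equilibrium")
  eq <- att$phase0_state
  for (bm in c(0.15, 0.25)) {
    hand <- unname(birth_rate(tr, bm) - p$q0 * (eq[1] + eq[2]) - p$b -
                     bm * eq[2])
    expect_equal(average_growth_fitness(p, tr, bm, att), hand,
                 tolerance = 1e-8)
    simple <- invasion_fitness("baseline", p, tr, bm, 0.2, attractor = att,
                               method = "simple_growth")
    expect_equal(simple$value, hand, tolerance = 1e-10)
  }
})

test_that("the next-generation closed form is sign-equivalent to the eigenvalue", {
  p <- fig2_epi(amp = 0)
  tr <- fig2_tradeoff()
  grid <- seq(0.2, 0.5, length.out = 12)
  for (br in grid) {
    expect_lt(abs(ngm_fitness_equilibrium(p, tr, br, br)), 1e-12)
    for (bm in grid) {
      s_ngm <- ngm_fitness_equilibrium(p, tr, bm, br)
      s_eig <- eigen_fitness_oracle(p, tr, bm, br)
      if (abs(s_ngm) > 1e-10 || abs(s_eig) > 1e-10)
        expect_identical(sign(s_ngm), sign(s_eig))
    }
  }
  psub <- p; psub$beta <- 0.1
  expect_error(ngm_fitness_equilibrium(psub, tr, 0.2, 0.1),
               class = "floquetad_disease_free")
})

test_that("Floquet multipliers envelope the long-run mutant trajectory", {
  p <- fig2_epi(amp = 0.5)
  tr <- fig2_tradeoff()
  p$beta <- 0.25
  att <- resident_attractor("seasonal", p, tr)
  for (bm in c(0.24, 0.27)) {      # one invading, one failing mutant
    mu <- monodromy_matrix(att, bm)$exponent
    ## integrate resident + mutant over five periods, sampling period ends
    func <- function(t, y, d) {
      dres <- resident_rhs("seasonal", p, t, y[1:2], tr)
      dm <- mutant_rhs("seasonal", p, tr, bm, t, y[3:4], y[1:2])
      list(c(dres, dm))
    }
    out <- deSolve::ode(c(att$phase0_state, 1, 0),
                        att$t0 + (0:5) * att$period, func, NULL,
                        rtol = 1e-9, atol = 1e-11, maxsteps = 5e5)
    norms <- sqrt(rowSums(out[, 4:5]^2))
    ## after transients the per-period log growth settles on T mu
    incr <- diff(log(norms))
    expect_lt(max(abs(incr[3:5] - mu * att$period)), 5e-3)
  }
})

test_that("invasion fitness signs flip across an invasion boundary", {
  p <- fig2_epi(amp = 0.5)
  tr <- fig2_tradeoff()
  ## resident above the singular point: downward mutants invade
  p$beta <- 0.25
  att <- resident_attractor("seasonal", p, tr)
  s_dn <- invasion_fitness("seasonal", p, tr, 0.24, 0.25, attractor = att)
  s_up <- invasion_fitness("seasonal", p, tr, 0.26, 0.25, attractor = att)
  expect_gt(s_dn$value, 0)
  expect_lt(s_up$value, 0)
})

test_that("fitness dispatch honours the attractor kind and failure modes", {
  p <- fig2_epi(amp = 0)
  tr <- fig2_tradeoff()
  s <- invasion_fitness("baseline", p, tr, 0.25, 0.3)
  expect_identical(s$method, "eigen")
  p5 <- fig2_epi(amp = 0.5)
  s5 <- invasion_fitness("seasonal", p5, tr, 0.25, 0.3)
  expect_identical(s5$method, "floquet")
  ## disease-free resident: fitness undefined
  expect_error(invasion_fitness("baseline", p, tr, 0.2, 0.05),
               class = "floquetad_disease_free")
  ## ngm is the baseline closed form only
  expect_error(invasion_fitness("seasonal", p5, tr, 0.25, 0.3,
                                method = "ngm"), "baseline")
  ## mismatched attractor is refused
  att <- resident_attractor("baseline", p, tr, warm_start = c(1, 1))
  expect_error(invasion_fitness("baseline", p, tr, 0.25, 0.4,
                                attractor = att), "different")
})
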