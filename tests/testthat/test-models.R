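test_that("trade-off birth rate matches its closed form and derivatives", {
  tr <- fig2_tradeoff()
  expect_identical(birth_rate(tr, 0.2), 10)
  ## hand evaluation of the closed form at beta = 0.3 with accelerating
  ## curvature: 10 - (1.58^2/3)(1 - exp(0.1 * 3 / 1.58))
  tr_acc <- fig2_tradeoff(tau2 = 3)
  expect_equal(birth_rate(tr_acc, 0.3), 10.17400, tolerance = 1e-5)
  ## first and second derivatives at the reference equal tau1 and tau2
  h <- 1e-5
  for (tau2 in c(-3, 3)) {
    tri <- fig2_tradeoff(tau2)
    d1 <- (birth_rate(tri, 0.2 + h) - birth_rate(tri, 0.2 - h)) / (2 * h)
    d2 <- (birth_rate(tri, 0.2 + h) - 2 * birth_rate(tri, 0.2) +
             birth_rate(tri, 0.2 - h)) / h^2
    expect_equal(d1, tri$tau1, tolerance = 1e-6)
    expect_equal(d2, tri$tau2, tolerance = 1e-3)
  }
  expect_error(tradeoff_params(10, 0.2, tau1 = 1.58, tau2 = 0), "tau2")
  expect_error(tradeoff_params(10, 0.2, tau1 = -1, tau2 = -3), "tau1")
})

test_that("seasonal competition forcing has amplitude and period one", {
  expect_identical(seasonal_competition(0.5, 0.5, 0), 0.5)
  expect_equal(seasonal_competition(0.5, 0.5, 0.25), 0.75)
  expect_identical(seasonal_competition(0.5, 0, 123.4), 0.5)
  tt <- seq(0, 3, by = 0.1)
  expect_equal(seasonal_competition(0.3, 0.8, tt),
               seasonal_competition(0.3, 0.8, tt + 1))
  expect_error(seasonal_competition(0.5, 1.5, 0), "amp")
})

test_that("parameter containers validate their invariants", {
  expect_error(epi_params(amp = 1.2), "amp")
  expect_error(epi_params(b = -1), "non-negative")
  expect_silent(epi_params(amp = 1))
})

test_that("resident derivatives vanish at the closed-form endemic equilibrium", {
  p <- fig2_epi(amp = 0)
  eq <- analytic_equilibrium(p)
  expect_equal(eq[["S"]], 15)
  expect_equal(eq[["I"]], 22.5 / 9.5)
  d <- resident_rhs("baseline", p, 0, eq)
  expect_lt(max(abs(d)), 1e-12)
  ## extinction is invariant
  expect_identical(resident_rhs("baseline", p, 0, c(0, 0)), c(0, 0))
  ## no shedding, no decay
  p4 <- fig4_epi()
  d4 <- resident_rhs("free_living", p4, 0, c(2, 0, 0))
  expect_identical(d4[3], 0)
  ## wrong state dimension is rejected
  expect_error(resident_rhs("baseline", p, 0, c(1, 1, 1)), "state")
  expect_error(resident_rhs("free_living", p4, 0, c(1, 1)), "state")
})

test_that("the basic reproduction number follows the closed form", {
  p <- fig2_epi(amp = 0)
  expect_equal(basic_reproduction_number(p), 1.2)
  p0 <- p; p0$beta <- 0
  expect_equal(basic_reproduction_number(p0), 0)
  expect_error(basic_reproduction_number(epi_params(a0 = 1, b = 2)),
               "viable")
  ## subcritical: endemic equilibrium rejected as disease-free
  psub <- p; psub$beta <- 0.1
  expect_lt(basic_reproduction_number(psub), 1)
  expect_error(analytic_equilibrium(psub), class = "floquetad_disease_free")
})

test_that("log dynamics are the change of variables of the direct system", {
  p <- fig2_epi(amp = 0.5)
  p4 <- fig4_epi()
  cases <- list(
    list(v = "baseline", p = fig2_epi(0), y = c(3, 1.5)),
    list(v = "seasonal", p = p, y = c(4, 0.8)),
    list(v = "seasonal_births", p = p, y = c(2.5, 2)),
    list(v = "free_living", p = p4, y = c(5, 2, 30)))
  for (cs in cases) {
    dn <- resident_rhs(cs$v, cs$p, 0.3, cs$y)
    dl <- log_rhs(cs$v, cs$p, 0.3, log(cs$y))
    ## d exp(X)/dt = exp(X) dX/dt must equal the direct derivative
    expect_equal(cs$y * dl, dn, tolerance = 1e-12, label = cs$v)
  }
})

test_that("log and direct integration agree on the free-living trajectory", {
  p <- fig4_epi()
  times <- seq(0, 50, by = 0.1)
  y0 <- c(1, 1, 1)
  direct <- deSolve::ode(y0, times,
                         function(t, y, d) list(resident_rhs("free_living", p, t, y)),
                         NULL, rtol = 1e-10, atol = 1e-12, maxsteps = 5e5)
  logged <- deSolve::ode(log(y0), times,
                         function(t, y, d) list(log_rhs("free_living", p, t, y)),
                         NULL, rtol = 1e-10, atol = 1e-12, maxsteps = 5e5)
  nat <- exp(logged[, -1])
  keep <- direct[, -1] > 1e-8
  rel <- abs(nat - direct[, -1]) / pmax(direct[, -1], 1e-8)
  expect_lt(max(rel[keep]), 1e-4)
})

test_that("trajectories preserve non-negativity from non-negative starts", {
  p <- fig2_epi(amp = 0.5)
  for (y0 in list(c(1, 1), c(0.01, 5), c(20, 0.001))) {
    out <- deSolve::ode(y0, seq(0, 100, by = 0.1),
                        function(t, y, d) list(resident_rhs("seasonal", p, t, y)),
                        NULL, rtol = 1e-8, atol = 1e-10, maxsteps = 5e5)
    expect_gt(min(out[, -1]), -1e-8)
  }
})
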