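test_that("the non-seasonal singular strategy sits at the calibrated trait", {
  p <- fig2_epi(amp = 0)
  tr <- fig2_tradeoff()
  sing <- find_singular_strategy("baseline", p, tr, bracket = c(0.1, 0.4))
  expect_lt(abs(sing$beta_star - 0.2), 0.005)
  ## self-consistency: gradient at the root is below tolerance
  g <- selection_gradient("baseline", p, tr, sing$beta_star)
  expect_lt(abs(g), 0.05)            # gradient slope ~40, bracket tol 1e-4
  expect_identical(sing$kind, "equilibrium")
})

test_that("selection points downhill toward the singular strategy", {
  p <- fig2_epi(amp = 0)
  tr <- fig2_tradeoff()
  expect_lt(selection_gradient("baseline", p, tr, 0.3), 0)
  expect_gt(selection_gradient("baseline", p, tr, 0.18), 0)
  ## finite-difference step robustness away from the singular point
  g1 <- selection_gradient("baseline", p, tr, 0.3, h = 1e-3)
  g2 <- selection_gradient("baseline", p, tr, 0.3, h = 5e-4)
  expect_lt(abs(g1 - g2) / abs(g1), 0.05)
})

test_that("the located singular strategy does not depend on the bracket", {
  p <- fig2_epi(amp = 0)
  tr <- fig2_tradeoff()
  s1 <- find_singular_strategy("baseline", p, tr, c(0.1, 0.4), tol = 1e-4)
  s2 <- find_singular_strategy("baseline", p, tr, c(0.15, 0.45), tol = 1e-4)
  expect_lt(abs(s1$beta_star - s2$beta_star), 2e-4)
  ## no sign change: clean failure
  expect_error(find_singular_strategy("baseline", p, tr, c(0.3, 0.45)),
               "no interior singular point")
})

test_that("trade-off curvature flips a CSS into a branching point", {
  p <- fig2_epi(amp = 0)
  for (tau2 in c(-3, 3)) {
    tr <- fig2_tradeoff(tau2)
    sing <- find_singular_strategy("baseline", p, tr, c(0.1, 0.4))
    cls <- classify_singular_strategy("baseline", p, tr, sing$beta_star)
    expect_identical(cls$label, if (tau2 < 0) "CSS" else "branching")
    expect_true(cls$converg_stable)
    expect_identical(cls$evol_stable, tau2 < 0)
    ## curvature sign oracle: finite differences of the closed-form
    ## next-generation fitness (sign-equivalent at a singular point)
    h <- 5e-3
    bs <- sing$beta_star
    curv <- (ngm_fitness_equilibrium(p, tr, bs + h, bs) -
               2 * ngm_fitness_equilibrium(p, tr, bs, bs) +
               ngm_fitness_equilibrium(p, tr, bs - h, bs)) / h^2
    expect_identical(sign(cls$es_curvature), sign(curv))
  }
})

test_that("the PIP diagonal is neutral and matches the equilibrium closed form", {
  p <- fig2_epi(amp = 0)
  tr <- fig2_tradeoff()
  pip <- pairwise_invasion_plot("baseline", p, tr,
                                trait_range = c(0.2, 0.45), n = 21L)
  expect_false(any(pip$flagged))
  expect_true(all(abs(diag(pip$fitness)) < pip$zero_tolerance))
  expect_true(all(diag(pip$sign_matrix) == 0))
  ## off-diagonal signs agree with the closed-form oracle
  for (j in c(1L, 8L, 15L, 21L)) {
    for (i in c(3L, 11L, 19L)) {
      if (i == j) next
      s_oracle <- ngm_fitness_equilibrium(p, tr, pip$trait_values[i],
                                          pip$trait_values[j])
      expect_identical(sign(pip$fitness[i, j]), sign(s_oracle))
    }
  }
  df <- as.data.frame(pip)
  expect_identical(nrow(df), 21L * 21L)
  expect_named(df, c("beta_r", "beta_m", "fitness", "sign"))
})

test_that("disease-free resident columns are flagged, not zeroed", {
  p <- fig2_epi(amp = 0)
  tr <- fig2_tradeoff()
  ## residents below beta ~ 0.167 are subcritical under this trade-off
  pip <- pairwise_invasion_plot("baseline", p, tr,
                                trait_range = c(0.1, 0.3), n = 21L)
  expect_true(any(pip$flagged))
  expect_true(all(is.na(pip$fitness[, pip$flagged])))
  expect_true(all(!is.na(pip$fitness[, !pip$flagged])))
})

test_that("parameter sweeps track the singular strategy by continuation", {
  p <- fig2_epi(amp = 0)
  tr <- fig2_tradeoff()
  sweep <- css_parameter_sweep("baseline", p, tr, param = "q0",
                               values = c(0.4, 0.5, 0.6),
                               bracket = c(0.1, 0.4))
  expect_identical(sweep$status, rep("ok", 3))
  ## continuation agrees with direct location at each swept value
  for (i in seq_len(nrow(sweep))) {
    p_i <- p; p_i$q0 <- sweep$value[i]
    direct <- find_singular_strategy("baseline", p_i, tr, c(0.1, 0.4))
    expect_lt(abs(sweep$beta_star[i] - direct$beta_star), 1e-3)
  }
})
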