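## Mutant invasion fitness.
##
## On a limit-cycle attractor, a rare mutant's dynamics are a linear
## time-periodic system in (S_m, I_m): its long-run growth is governed by the
## Floquet exponents, obtained from the monodromy matrix C that maps the
## mutant state across one period. On an equilibrium attractor the same
## object degenerates to the dominant eigenvalue of the constant mutant
## Jacobian, and with no recovery the mutant is unstructured and the exponent
## equals the period-averaged per-capita growth rate.

## mutant birth rate (trait cost applied; seasonal_births also forced)
.mutant_a <- function(variant, p, tr, beta_m, t) {
  a <- if (is.null(tr)) p$a0 else birth_rate(tr, beta_m)
  a * .births_forcing(variant, p, t)
}

## constant-coefficient mutant Jacobian at a given resident state and time
.mutant_jacobian <- function(variant, p, tr, beta_m, t, res_state) {
  S <- res_state[1L]; I <- res_state[2L]
  FF <- if (variant == "free_living") res_state[3L] else I
  q <- .q_at(variant, p, t)
  k <- p$b + p$alpha + p$gamma
  g1 <- .mutant_a(variant, p, tr, beta_m, t) - q * (S + I) - p$b - beta_m * FF
  matrix(c(g1, p$gamma, beta_m * FF, -k), 2L, 2L, byrow = TRUE)
}

#' Rare-mutant right-hand side
#'
#' Time derivatives of the rare mutant densities \eqn{(S_m, I_m)} in the
#' environment set by the resident attractor: a linear time-varying system
#' \deqn{dS_m/dt = (a(\beta_m) - q(t)(S^*+I^*))S_m - bS_m - \beta_m S_m F^*
#'   + \gamma I_m, \quad dI_m/dt = \beta_m S_m F^* - (b+\alpha+\gamma)I_m,}
#' with \eqn{F^* = I^*(t)} for direct transmission and \eqn{F^* = P^*(t)}
#' for the free-living variant. Mutant-mutant interactions are absent (the
#' mutant is rare), so the system is linear in the mutant state; mutant
#' shedding into the shared free-living pool is likewise negligible at
#' invasion, keeping the mutant subsystem two-dimensional.
#'
#' @inheritParams resident_rhs
#' @param beta_m mutant transmission trait.
#' @param mutant_state mutant densities `c(Sm, Im)`.
#' @param resident_state resident densities on the attractor at time `t`.
#' @return Mutant derivatives `c(dSm, dIm)`.
#' @export
mutant_rhs <- function(variant, p, tr = NULL, beta_m, t, mutant_state,
                       resident_state) {
  variant <- .check_variant(variant)
  stopifnot(inherits(p, "epi_params"), length(mutant_state) == 2L,
            length(resident_state) == .n_state(variant))
  drop(.mutant_jacobian(variant, p, tr, beta_m, t, resident_state) %*%
         mutant_state)
}

## combined resident + two-mutant-copy system used by the monodromy
## integration; resident is co-integrated from the attractor's stored state
## so that no interpolation of the stored cycle is needed
.monodromy_integrate <- function(cyc, beta_m, init, t_start, y_start,
                                 T, rtol, atol) {
  variant <- cyc$variant
  p <- cyc$p
  tr <- cyc$tr
  nres <- .n_state(variant)
  uselog <- variant == "free_living"
  k <- p$b + p$alpha + p$gamma
  a_m0 <- if (is.null(tr)) p$a0 else birth_rate(tr, beta_m)
  forced_births <- variant == "seasonal_births"
  func <- function(t, y, parms) {
    res <- y[seq_len(nres)]
    dres <- if (uselog) log_rhs(variant, p, t, res, tr)
            else resident_rhs(variant, p, t, res, tr)
    nat <- if (uselog) exp(res) else res
    S <- nat[1L]; I <- nat[2L]
    FF <- if (uselog) nat[3L] else I
    q <- .q_at(variant, p, t)
    a_m <- if (forced_births) a_m0 * (1 + p$amp * sin(2 * pi * t)) else a_m0
    g1 <- a_m - q * (S + I) - p$b - beta_m * FF
    g21 <- beta_m * FF
    m <- y[(nres + 1L):(nres + 4L)]
    dm <- c(g1 * m[1L] + p$gamma * m[2L], g21 * m[1L] - k * m[2L],
            g1 * m[3L] + p$gamma * m[4L], g21 * m[3L] - k * m[4L])
    list(c(dres, dm))
  }
  y0 <- c(if (uselog) log(y_start) else y_start, as.vector(init))
  out <- deSolve::ode(y0, c(t_start, t_start + T), func, NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 500000)
  if (attr(out, "istate")[1L] < 0 || nrow(out) < 2L)
    stop("monodromy integration failed")
  yend <- out[2L, -1L]
  res_end <- yend[seq_len(nres)]
  if (uselog) res_end <- exp(res_end)
  list(res_end = res_end,
       mutant_end = matrix(yend[(nres + 1L):(nres + 4L)], 2L, 2L))
}

#' Monodromy matrix of the mutant subsystem on the resident cycle
#'
#' Co-integrates the resident equations (from the attractor's stored phase-0
#' state) together with two copies of the linear mutant system over exactly
#' one period, starting from linearly independent mutant initial conditions
#' (by default the unit vectors `[1,0]` and `[0,1]`). The matrix `C` whose
#' columns are the mutant end states maps the mutant state across one period;
#' its eigenvalues are the Floquet multipliers \eqn{\rho_i = e^{\mu_i T}} and
#' the dominant Floquet exponent is \eqn{\mu = \ln(\rho_{max})/T}, normalized
#' per unit time so that exponents are comparable across attractors with
#' different periods.
#'
#' For a non-default `init` basis `M`, `C` is recovered as
#' \eqn{Y(T) M^{-1}}, so the multipliers are invariant to the choice of
#' linearly independent initial conditions.
#'
#' @param attractor a `cycle_attractor` from [resident_attractor()];
#'   equilibrium attractors are handled as degenerate constant cycles.
#' @param beta_m mutant transmission trait.
#' @param init 2x2 matrix of mutant initial conditions (columns); must be
#'   non-singular.
#' @param start_index index into the attractor grid at which to start the
#'   period integration (the exponent is invariant to this phase).
#' @param rtol,atol solver tolerances.
#' @param drift_tol maximum relative drift of the co-integrated resident
#'   over the period before a convergence warning is issued.
#' @return An object of class `monodromy_result` with fields `C`,
#'   `multipliers`, `exponent`, `period_used` and `resident_gap`.
#' @export
monodromy_matrix <- function(attractor, beta_m, init = diag(2),
                             start_index = 1L, rtol = NULL, atol = NULL,
                             drift_tol = 1e-3) {
  stopifnot(inherits(attractor, "cycle_attractor"))
  if (!is.matrix(init) || any(dim(init) != 2L) ||
      abs(det(init)) < 1e-12)
    stop("monodromy_matrix: init must be a non-singular 2x2 matrix")
  if (is.null(rtol)) rtol <- attractor$rtol
  if (is.null(atol)) atol <- attractor$atol
  T <- attractor$period
  y_start <- attractor$states[start_index, ]
  t_start <- attractor$t0 + attractor$times[start_index]
  if (T <= 0) {
    C <- diag(2)
    return(structure(list(C = C, multipliers = c(1, 1), exponent = 0,
                          period_used = 0, resident_gap = 0,
                          beta_m = beta_m),
                     class = "monodromy_result"))
  }
  res <- .monodromy_integrate(attractor, beta_m, init, t_start, y_start,
                              T, rtol, atol)
  gap <- max(abs(res$res_end - y_start) / pmax(abs(y_start), 1e-12))
  if (attractor$kind == "cycle" && gap > drift_tol)
    warning("monodromy_matrix: resident drifted off the attractor (gap ",
            signif(gap, 3), "); attractor not converged")
  C <- res$mutant_end %*% solve(init)
  multipliers <- eigen(C, only.values = TRUE)$values
  imax <- which.max(Mod(multipliers))
  rho <- multipliers[imax]
  if (is.complex(rho) && abs(Im(rho)) > 1e-8 * max(1, Mod(rho)))
    warning("monodromy_matrix: dominant multiplier has a non-negligible ",
            "imaginary part; using its modulus (positivity assumption ",
            "violated)")
  structure(list(C = C, multipliers = multipliers,
                 exponent = log(Mod(rho)) / T, period_used = T,
                 resident_gap = gap, beta_m = beta_m),
            class = "monodromy_result")
}

#' @export
print.monodromy_result <- function(x, ...) {
  cat(sprintf(
    "<monodromy_result> beta_m = %g over period %g\n", x$beta_m,
    x$period_used))
  cat("multipliers:", paste(signif(x$multipliers, 6), collapse = ", "), "\n")
  cat(sprintf("dominant Floquet exponent: %.6g per unit time\n", x$exponent))
  invisible(x)
}

#' Closed-form equilibrium invasion fitness (next-generation form)
#'
#' The next-generation invasion criterion for the non-seasonal
#' direct-transmission model at its endemic equilibrium,
#' \deqn{s(\beta_m, \beta) = \frac{a(\beta_m) - q(S^*+I^*)}{b + \beta_m I^*}
#'  + \frac{\gamma \beta_m I^*}{(b + \beta_m I^*)(\alpha + b + \gamma)} - 1:}
#' the expected lifetime offspring of a mutant susceptible (first term) plus
#' the probability of surviving one infection-recovery loop (second term),
#' minus one. Zero for a mutant identical to the resident and
#' sign-equivalent to the dominant-eigenvalue criterion, but a
#' per-generation quantity: use the eigenvalue (or Floquet) fitness for
#' per-unit-time growth rates.
#'
#' @inheritParams resident_rhs
#' @param beta_m mutant trait.
#' @param beta_r resident trait.
#' @return The next-generation fitness value (a single number).
#' @export
ngm_fitness_equilibrium <- function(p, tr = NULL, beta_m, beta_r) {
  stopifnot(inherits(p, "epi_params"))
  p$beta <- beta_r
  eq <- analytic_equilibrium(p, tr)
  a_m <- if (is.null(tr)) p$a0 else birth_rate(tr, beta_m)
  k <- p$b + p$alpha + p$gamma
  D <- p$b + beta_m * eq[["I"]]
  (a_m - p$q0 * (eq[["S"]] + eq[["I"]])) / D +
    p$gamma * beta_m * eq[["I"]] / (D * k) - 1
}

#' Period-averaged growth-rate fitness (no recovery)
#'
#' With no recovery (\eqn{\gamma = 0}) the rare mutant is unstructured --
#' only \eqn{S_m} contributes to invasion -- and its fitness is the average
#' per-capita growth rate over one resident cycle,
#' \deqn{\bar r = \frac{1}{T}\int_0^T \big(a(\beta_m, t)
#'   - q(t)(S^*(t)+I^*(t)) - \beta_m F^*(t)\big)\,dt - b.}
#' The integral is accumulated by co-integrating the resident equations with
#' an auxiliary quadrature state over one stored period, so its accuracy
#' matches the solver tolerance. For scalar linear systems this equals the
#' Floquet exponent exactly, which makes it an independent cross-check of
#' the monodromy route.
#'
#' @inheritParams ngm_fitness_equilibrium
#' @param attractor a `cycle_attractor` for the resident.
#' @param rtol,atol solver tolerances.
#' @return The period-averaged growth rate (a single number).
#' @export
average_growth_fitness <- function(p, tr = NULL, beta_m, attractor,
                                   rtol = NULL, atol = NULL) {
  stopifnot(inherits(attractor, "cycle_attractor"))
  if (p$gamma != 0)
    stop("average_growth_fitness: only valid for gamma = 0 ",
         "(unstructured mutant); use the Floquet fitness otherwise")
  if (is.null(rtol)) rtol <- attractor$rtol
  if (is.null(atol)) atol <- attractor$atol
  variant <- attractor$variant
  nres <- .n_state(variant)
  uselog <- variant == "free_living"
  a_m0 <- if (is.null(tr)) p$a0 else birth_rate(tr, beta_m)
  forced_births <- variant == "seasonal_births"
  T <- attractor$period
  func <- function(t, y, parms) {
    res <- y[seq_len(nres)]
    dres <- if (uselog) log_rhs(variant, p, t, res, tr)
            else resident_rhs(variant, p, t, res, tr)
    nat <- if (uselog) exp(res) else res
    FF <- if (uselog) nat[3L] else nat[2L]
    a_m <- if (forced_births) a_m0 * (1 + p$amp * sin(2 * pi * t)) else a_m0
    r <- a_m - .q_at(variant, p, t) * (nat[1L] + nat[2L]) - beta_m * FF - p$b
    list(c(dres, r))
  }
  y_start <- attractor$phase0_state
  y0 <- c(if (uselog) log(y_start) else y_start, 0)
  out <- deSolve::ode(y0, attractor$t0 + c(0, T), func, NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 500000)
  unname(out[2L, ncol(out)]) / T
}

#' Invasion fitness of a rare mutant host
#'
#' Long-run per-capita growth rate of a rare mutant with trait `beta_m` in
#' the environment set by a resident with trait `beta_r` at its ecological
#' attractor. On a limit cycle this is the dominant Floquet exponent of the
#' mutant subsystem ([monodromy_matrix()]); on an equilibrium it is the
#' dominant eigenvalue of the constant mutant Jacobian (the zero-amplitude
#' limit of the Floquet exponent). A mutant can invade when the fitness is
#' positive; a strain invading itself has fitness zero.
#'
#' @inheritParams resident_rhs
#' @param beta_m mutant trait.
#' @param beta_r resident trait (`p$beta` is overridden with this value).
#' @param attractor optional pre-computed resident `cycle_attractor` (must
#'   match `beta_r`); computed via [resident_attractor()] if missing.
#' @param method `"auto"` (equilibrium attractor: dominant eigenvalue;
#'   cycle: Floquet), or one of `"floquet"`, `"eigen"`, `"average_growth"`
#'   (requires `gamma = 0`), `"simple_growth"` (the constant-coefficient
#'   no-recovery growth rate, requires an equilibrium and `gamma = 0`) or
#'   `"ngm"` (the closed-form next-generation expression; per-generation
#'   scale, baseline variant only).
#' @param ... passed to [resident_attractor()] when the attractor is built
#'   internally.
#' @return An object of class `invasion_fitness` with fields `value`,
#'   `beta_m`, `beta_r` and `method`.
#' @export
invasion_fitness <- function(variant, p, tr = NULL, beta_m, beta_r,
                             attractor = NULL, method = "auto", ...) {
  variant <- .check_variant(variant)
  method <- match.arg(method, c("auto", "floquet", "eigen",
                                "average_growth", "simple_growth", "ngm"))
  p$beta <- beta_r
  if (method == "ngm") {
    if (variant != "baseline")
      stop("invasion_fitness: method 'ngm' is the closed equilibrium form ",
           "of the baseline variant")
    val <- ngm_fitness_equilibrium(p, tr, beta_m, beta_r)
    return(.fitness_obj(val, beta_m, beta_r, "ngm"))
  }
  if (is.null(attractor)) {
    attractor <- resident_attractor(variant, p, tr, ...)
  } else {
    stopifnot(inherits(attractor, "cycle_attractor"))
    if (abs(attractor$p$beta - beta_r) > 1e-12 ||
        attractor$variant != variant)
      stop("invasion_fitness: supplied attractor was built for a different ",
           "resident (beta = ", attractor$p$beta, ", variant = ",
           attractor$variant, ")")
  }
  if (method == "auto")
    method <- if (attractor$kind == "equilibrium") "eigen" else "floquet"
  val <- switch(method,
    floquet = monodromy_matrix(attractor, beta_m)$exponent,
    eigen = {
      if (attractor$kind != "equilibrium")
        stop("invasion_fitness: method 'eigen' needs an equilibrium ",
             "attractor; the resident is on a cycle")
      J <- .mutant_jacobian(variant, p, tr, beta_m, attractor$t0,
                            attractor$phase0_state)
      max(Re(eigen(J, only.values = TRUE)$values))
    },
    average_growth = average_growth_fitness(p, tr, beta_m, attractor),
    simple_growth = {
      if (attractor$kind != "equilibrium" || p$gamma != 0)
        stop("invasion_fitness: method 'simple_growth' needs gamma = 0 and ",
             "an equilibrium attractor")
      st <- attractor$phase0_state
      FF <- if (variant == "free_living") st[3L] else st[2L]
      .mutant_a(variant, p, tr, beta_m, attractor$t0) -
        .q_at(variant, p, attractor$t0) * (st[1L] + st[2L]) -
        p$b - beta_m * FF
    })
  .fitness_obj(val, beta_m, beta_r, method)
}

.fitness_obj <- function(value, beta_m, beta_r, method) {
  structure(list(value = unname(value), beta_m = beta_m, beta_r = beta_r,
                 method = method),
            class = "invasion_fitness")
}

#' @export
print.invasion_fitness <- function(x, ...) {
  cat(sprintf("invasion fitness s(%g, %g) = %.6g  [%s]%s\n",
              x$beta_m, x$beta_r, x$value, x$method,
              if (x$value > 0) "  -> mutant can invade" else ""))
  invisible(x)
}

## bare-number fitness used by the adaptive-dynamics loops
.fitness_value <- function(variant, p, tr, beta_m, beta_r, attractor,
                           method = "auto") {
  invasion_fitness(variant, p, tr, beta_m, beta_r, attractor,
                   method = method)$value
}
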