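## Model variants
##   baseline        -- constant-parameter SIS with crowding (2 states: S, I)
##   seasonal        -- competition forced, q(t) = q0(1 + amp sin 2 pi t)
##   seasonal_births -- birth rate forced, a(t) = a(beta)(1 + amp sin 2 pi t)
##   free_living     -- transmission via free-living stages (3 states: S, I, P)

MODEL_VARIANTS <- c("baseline", "seasonal", "seasonal_births", "free_living")

.check_variant <- function(variant) {
  match.arg(variant, MODEL_VARIANTS)
}

.n_state <- function(variant) {
  if (variant == "free_living") 3L else 2L
}

.is_forced <- function(variant) {
  variant %in% c("seasonal", "seasonal_births")
}

## resident birth rate at the resident trait (before any seasonal forcing)
.res_a <- function(p, tr) {
  if (is.null(tr)) p$a0 else birth_rate(tr, p$beta)
}

## time-dependent coefficients shared by resident and mutant equations
.q_at <- function(variant, p, t) {
  if (variant == "seasonal") seasonal_competition(p$q0, p$amp, t) else p$q0
}

.births_forcing <- function(variant, p, t) {
  if (variant == "seasonal_births") 1 + p$amp * sin(2 * pi * t) else 1
}

#' Resident model right-hand side
#'
#' Time derivatives of the resident densities for the chosen model variant.
#' The susceptible equation is
#' \eqn{dS/dt = (a - q(S+I))S - bS - \beta S F + \gamma I} and the infected
#' equation \eqn{dI/dt = \beta S F - (b+\alpha+\gamma) I}, where the force of
#' infection partner \eqn{F} is the infected density \eqn{I} for
#' direct-transmission variants and the free-living stage density \eqn{P} for
#' `free_living`, which adds \eqn{dP/dt = \theta I - \mathrm{decay}\, P}.
#' For `seasonal`, the competition coefficient is
#' [seasonal_competition()]; for `seasonal_births` the birth rate is forced
#' instead.
#'
#' @param variant one of `"baseline"`, `"seasonal"`, `"seasonal_births"`,
#'   `"free_living"`.
#' @param p an [epi_params()] object.
#' @param t time.
#' @param state density vector `c(S, I)` or `c(S, I, P)`.
#' @param tr optional [tradeoff_params()]; when given, the resident birth
#'   rate is `birth_rate(tr, p$beta)` instead of `p$a0`.
#' @return Vector of time derivatives, same length as `state`.
#' @seealso [log_rhs()], [analytic_equilibrium()]
#' @export
resident_rhs <- function(variant, p, t, state, tr = NULL) {
  variant <- .check_variant(variant)
  stopifnot(inherits(p, "epi_params"))
  if (length(state) != .n_state(variant))
    stop("resident_rhs: variant '", variant, "' expects ",
         .n_state(variant), " state variables, got ", length(state))
  S <- state[1L]; I <- state[2L]
  a <- .res_a(p, tr) * .births_forcing(variant, p, t)
  q <- .q_at(variant, p, t)
  k <- p$b + p$alpha + p$gamma
  FF <- if (variant == "free_living") state[3L] else I
  dS <- (a - q * (S + I)) * S - p$b * S - p$beta * S * FF + p$gamma * I
  dI <- p$beta * S * FF - k * I
  if (variant == "free_living") {
    dP <- p$theta * I - p$decay * state[3L]
    c(dS, dI, dP)
  } else {
    c(dS, dI)
  }
}

#' Log-transformed resident right-hand side
#'
#' The same dynamics as [resident_rhs()] in log-density coordinates
#' \eqn{X = \ln S}, \eqn{Y = \ln I} (and \eqn{Z = \ln P} for `free_living`).
#' The log transform tames the stiffness of cycling systems whose densities
#' range over several orders of magnitude within a period, and is the
#' recommended representation for long integrations of the free-living model.
#'
#' @inheritParams resident_rhs
#' @param logstate log-density vector (unconstrained).
#' @return Vector of log-density derivatives.
#' @export
log_rhs <- function(variant, p, t, logstate, tr = NULL) {
  variant <- .check_variant(variant)
  stopifnot(inherits(p, "epi_params"))
  if (length(logstate) != .n_state(variant))
    stop("log_rhs: variant '", variant, "' expects ",
         .n_state(variant), " state variables, got ", length(logstate))
  X <- logstate[1L]; Y <- logstate[2L]
  a <- .res_a(p, tr) * .births_forcing(variant, p, t)
  q <- .q_at(variant, p, t)
  k <- p$b + p$alpha + p$gamma
  S <- exp(X); I <- exp(Y)
  if (variant == "free_living") {
    Z <- logstate[3L]
    dX <- a - q * (S + I) - p$b - p$beta * exp(Z) + p$gamma * exp(Y - X)
    dY <- p$beta * exp(X + Z - Y) - k
    dZ <- p$theta * exp(Y - Z) - p$decay
    c(dX, dY, dZ)
  } else {
    dX <- a - q * (S + I) - p$b - p$beta * I + p$gamma * exp(Y - X)
    dY <- p$beta * S - k
    c(dX, dY)
  }
}

#' Basic reproduction number of the parasite
#'
#' \eqn{R_0 = \beta S_{dfe} / (b + \alpha + \gamma)} for direct transmission,
#' with the disease-free host density \eqn{S_{dfe} = (a_0 - b)/q_0} (the
#' positive root of the disease-free host dynamics). For the `free_living`
#' variant each infected host sheds \eqn{\theta/\mathrm{decay}} surviving
#' stages' worth of exposure, giving
#' \eqn{R_0 = \beta \theta S_{dfe} / ((b+\alpha+\gamma)\,\mathrm{decay})}.
#'
#' @inheritParams resident_rhs
#' @return The basic reproduction number (a single number).
#' @export
basic_reproduction_number <- function(p, variant = "baseline", tr = NULL) {
  variant <- .check_variant(variant)
  stopifnot(inherits(p, "epi_params"))
  a <- .res_a(p, tr)
  if (a <= p$b)
    stop("basic_reproduction_number: host population not viable (a0 <= b)")
  S_dfe <- (a - p$b) / p$q0
  k <- p$b + p$alpha + p$gamma
  if (variant == "free_living") {
    if (p$decay <= 0)
      stop("basic_reproduction_number: free_living variant needs decay > 0")
    p$beta * p$theta * S_dfe / (k * p$decay)
  } else {
    p$beta * S_dfe / k
  }
}

#' Endemic equilibrium of the non-seasonal direct-transmission model
#'
#' Closed-form endemic equilibrium of the baseline model:
#' \eqn{S^* = (b+\alpha+\gamma)/\beta} and
#' \eqn{I^* = (a - qS^* - b)S^* / ((q+\beta)S^* - \gamma)}, the fixed point of
#' [resident_rhs()] for `variant = "baseline"` when \eqn{R_0 > 1}.
#'
#' @inheritParams resident_rhs
#' @return Named vector `c(S = , I = )`.
#' @export
analytic_equilibrium <- function(p, tr = NULL) {
  stopifnot(inherits(p, "epi_params"))
  R0 <- basic_reproduction_number(p, "baseline", tr)
  if (R0 <= 1)
    stop(.disease_free_condition(
      sprintf("analytic_equilibrium: R0 = %.4g <= 1, endemic equilibrium does not exist (disease-free)",
              R0)))
  a <- .res_a(p, tr)
  k <- p$b + p$alpha + p$gamma
  S <- k / p$beta
  I <- (a - p$q0 * S - p$b) * S / ((p$q0 + p$beta) * S - p$gamma)
  c(S = S, I = I)
}

## classed error condition for subcritical (parasite-free) parameter sets,
## so grid/sweep code can catch it and flag rather than abort
.disease_free_condition <- function(msg) {
  structure(class = c("floquetad_disease_free", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
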