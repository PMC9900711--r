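#' Epidemiological parameters
#'
#' Container for the ecological and epidemiological rate constants shared by
#' all model variants. Rates are per unit time; densities are unscaled.
#'
#' @param a0 baseline (or reference) host birth rate.
#' @param q0 baseline competition (crowding) coefficient.
#' @param b natural host mortality rate.
#' @param alpha virulence: additional mortality of infected hosts.
#' @param gamma recovery rate of infected hosts (back to susceptible).
#' @param beta resident transmission coefficient (the evolving host trait).
#' @param amp seasonal forcing amplitude, in `[0, 1]`; only used by the
#'   `seasonal` and `seasonal_births` variants.
#' @param theta shedding rate of free-living parasite stages by infected
#'   hosts (`free_living` variant only).
#' @param decay decay rate of free-living parasite stages (`free_living`
#'   variant only).
#'
#' @return An object of class `epi_params` (a validated named list).
#' @seealso [tradeoff_params()], [resident_rhs()]
#' @examples
#' epi_params(a0 = 10, q0 = 0.5, b = 1, alpha = 1, gamma = 1, beta = 0.2)
#' @export
epi_params <- function(a0 = 10, q0 = 0.5, b = 1, alpha = 1, gamma = 1,
                       beta = 0.2, amp = 0, theta = 0, decay = 0) {
  p <- list(a0 = a0, q0 = q0, b = b, alpha = alpha, gamma = gamma,
            beta = beta, amp = amp, theta = theta, decay = decay)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("epi_params: '", nm, "' must be a single finite number")
    if (v < 0)
      stop("epi_params: '", nm, "' must be non-negative")
  }
  if (amp > 1)
    stop("epi_params: 'amp' must lie in [0, 1]")
  structure(p, class = "epi_params")
}

#' @export
print.epi_params <- function(x, ...) {
  cat("Epidemiological parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Birth-rate/transmission trade-off parameters
#'
#' The cost of host defence: lowering the transmission trait `beta` lowers the
#' birth rate through
#' \deqn{a(\beta) = a_{ref} - (\tau_1^2/\tau_2)\,
#'   \{1 - \exp((\beta - \beta_{ref})\,\tau_2/\tau_1)\},}
#' so that \eqn{a(\beta_{ref}) = a_{ref}}, \eqn{a'(\beta_{ref}) = \tau_1} and
#' \eqn{a''(\beta_{ref}) = \tau_2}. `tau1` sets the gradient of the trade-off
#' at the reference trait, `tau2` its curvature (negative: decelerating cost).
#'
#' @param a_ref birth rate at the reference trait.
#' @param beta_ref reference transmission value.
#' @param tau1 trade-off gradient at the reference (> 0).
#' @param tau2 trade-off curvature at the reference (non-zero).
#'
#' @return An object of class `tradeoff_params`.
#' @seealso [birth_rate()], [calibrate_tau1()]
#' @export
tradeoff_params <- function(a_ref = 10, beta_ref = 0.2, tau1, tau2) {
  if (!is.numeric(tau1) || length(tau1) != 1L || !is.finite(tau1) || tau1 <= 0)
    stop("tradeoff_params: 'tau1' must be a single positive number")
  if (!is.numeric(tau2) || length(tau2) != 1L || !is.finite(tau2) || tau2 == 0)
    stop("tradeoff_params: 'tau2' must be a single non-zero number ",
         "(the tau2 -> 0 linear limit is not supported)")
  structure(list(a_ref = a_ref, beta_ref = beta_ref,
                 tau1 = tau1, tau2 = tau2),
            class = "tradeoff_params")
}

#' @export
print.tradeoff_params <- function(x, ...) {
  cat(sprintf(
    "Trade-off a(beta): a_ref = %g at beta_ref = %g; a' = %g, a'' = %g\n",
    x$a_ref, x$beta_ref, x$tau1, x$tau2))
  invisible(x)
}

#' Birth rate under the defence trade-off
#'
#' Evaluates \eqn{a(\beta)} for the trade-off in [tradeoff_params()].
#' Monotone increasing in `beta` near the reference trait: more transmissible
#' (less defended) hosts reproduce faster.
#'
#' @param tr a [tradeoff_params()] object.
#' @param beta transmission trait value(s); vectorized.
#' @return Birth rate(s), same length as `beta`.
#' @examples
#' tr <- tradeoff_params(a_ref = 10, beta_ref = 0.2, tau1 = 1.58, tau2 = -3)
#' birth_rate(tr, 0.2)   # exactly a_ref
#' @export
birth_rate <- function(tr, beta) {
  stopifnot(inherits(tr, "tradeoff_params"))
  tr$a_ref - (tr$tau1^2 / tr$tau2) *
    (1 - exp((beta - tr$beta_ref) * tr$tau2 / tr$tau1))
}

#' Seasonally forced competition coefficient
#'
#' \eqn{q(t) = q_0 (1 + \delta \sin 2\pi t)}: sinusoidal forcing with period
#' exactly 1 time unit (one "year").
#'
#' @param q0 baseline competition coefficient.
#' @param amp forcing amplitude \eqn{\delta \in [0, 1]}.
#' @param t time (vectorized).
#' @return Competition coefficient(s) at time `t`.
#' @export
seasonal_competition <- function(q0, amp, t) {
  if (any(amp < 0 | amp > 1)) stop("seasonal_competition: amp must be in [0, 1]")
  q0 * (1 + amp * sin(2 * pi * t))
}

#' Calibrate the trade-off gradient so a given trait is singular
#'
#' Returns the trade-off gradient `tau1` that places an evolutionarily
#' singular strategy exactly at `beta_ref` in the non-seasonal
#' direct-transmission model at its endemic equilibrium. From the selection
#' gradient of the equilibrium invasion fitness, the singular condition is
#' \deqn{a'(\beta^*) = I^* (b + \alpha) / (b + \alpha + \gamma),}
#' with \eqn{I^*} the endemic infected density at `beta_ref` (and birth rate
#' `a_ref`). With the Figure-2-style defaults (q0 = 0.5) this gives 1.579,
#' i.e. the familiar rounded 1.58.
#'
#' @param p an [epi_params()] object (its `beta` is ignored).
#' @param beta_ref trait value to be made singular.
#' @param a_ref birth rate at `beta_ref`.
#' @return The calibrated `tau1` (a positive number).
#' @seealso [tradeoff_params()], [find_singular_strategy()]
#' @export
calibrate_tau1 <- function(p, beta_ref = 0.2, a_ref = 10) {
  stopifnot(inherits(p, "epi_params"))
  p2 <- p
  p2$beta <- beta_ref
  p2$a0 <- a_ref
  eq <- analytic_equilibrium(p2)
  tau1 <- eq[["I"]] * (p$b + p$alpha) / (p$b + p$alpha + p$gamma)
  if (tau1 <= 0) stop("calibrate_tau1: calibration gives non-positive tau1")
  tau1
}

.presets_path <- function() {
  system.file("extdata", "presets.json", package = "floquetad",
              mustWork = TRUE)
}

#' Named parameter presets for the worked examples
#'
#' `preset()` returns the full run configuration for one of the shipped
#' worked-example parameter sets, keyed by the figure it reproduces
#' (`"fig2a"`, `"fig2b"`, `"fig2c"`, `"fig3a"`, `"fig3b"`, `"fig4"`,
#' `"fig4b"`, `"fig5a"`, `"fig5b"`). `list_presets()` lists the available
#' keys.
#'
#' @param name preset key.
#' @return A configuration list with elements `variant`, `epi`
#'   (an [epi_params()]), optionally `tradeoff` (a [tradeoff_params()]),
#'   `trait_range`, `bracket`, and task-specific settings (e.g. `sweep`).
#' @examples
#' names(preset("fig4")$epi)
#' list_presets()
#' @export
preset <- function(name) {
  all <- jsonlite::read_json(.presets_path(), simplifyVector = TRUE)
  if (!name %in% names(all))
    stop("unknown preset '", name, "'; available: ",
         paste(names(all), collapse = ", "))
  cfg <- all[[name]]
  cfg$epi <- do.call(epi_params, as.list(cfg$epi))
  if (!is.null(cfg$tradeoff)) {
    td <- as.list(cfg$tradeoff)
    if (isTRUE(td$calibrate_tau1)) {
      td$calibrate_tau1 <- NULL
      td$tau1 <- calibrate_tau1(cfg$epi, beta_ref = td$beta_ref,
                                a_ref = td$a_ref)
    }
    cfg$tradeoff <- do.call(tradeoff_params, td)
  }
  cfg$preset <- name
  cfg
}

#' @rdname preset
#' @export
list_presets <- function() {
  names(jsonlite::read_json(.presets_path()))
}
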