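## Resident attractor machinery: burn-in integration, attractor
## classification (equilibrium vs limit cycle), numerical period detection,
## and resampling of one period into a canonical cycle object.

.default_state <- function(variant) {
  rep(1, .n_state(variant))
}

.state_names <- function(variant) {
  if (variant == "free_living") c("S", "I", "P") else c("S", "I")
}

## integrate the resident system on an absolute time grid, returning natural
## densities; the free-living variant is integrated in log coordinates
## (stiffness remedy), others directly
.integrate_resident <- function(variant, p, tr, y0, times,
                                rtol = 1e-9, atol = 1e-11) {
  uselog <- variant == "free_living"
  func <- if (uselog) {
    function(t, y, parms) list(log_rhs(variant, p, t, y, tr))
  } else {
    function(t, y, parms) list(resident_rhs(variant, p, t, y, tr))
  }
  y <- if (uselog) log(pmax(y0, 1e-300)) else y0
  out <- deSolve::ode(y, times, func, NULL, method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 500000)
  if (attr(out, "istate")[1L] < 0 || nrow(out) < length(times))
    stop("resident integration failed (solver diagnostic istate = ",
         attr(out, "istate")[1L], ")")
  st <- out[, -1L, drop = FALSE]
  if (uselog) st <- exp(st)
  colnames(st) <- .state_names(variant)
  list(times = out[, 1L], states = st)
}

#' Integrate the resident dynamics to their attractor
#'
#' Runs the resident system for `burn_in` time units from `warm_start` (or a
#' default interior point) and then records a densely sampled observation
#' window used downstream for attractor classification and period detection.
#' The free-living variant is integrated in log coordinates (see
#' [log_rhs()]); an adaptive solver suitable for stiff systems is used
#' throughout.
#'
#' @inheritParams resident_rhs
#' @param burn_in transient-discard duration (time units).
#' @param warm_start optional strictly positive initial densities; when
#'   looping over parameters, passing the previous end state shortens the
#'   transient considerably.
#' @param window length of the densely sampled post-burn-in window (time
#'   units); defaults to 60 (120 for `free_living`, whose intrinsic period is
#'   not known in advance).
#' @param dt sampling interval within the window.
#' @param rtol,atol solver tolerances.
#' @param floor density below which a compartment is considered collapsed;
#'   used to flag disease-free (parasite extinct) or host-extinct attractors.
#' @return An object of class `attractor_run`: the sampled window
#'   (`$times`, absolute; `$states`, natural densities), the `$end_state`,
#'   and collapse `$flags`.
#' @seealso [detect_period()], [resample_cycle()], [resident_attractor()]
#' @export
integrate_to_attractor <- function(variant, p, tr = NULL, burn_in = 500,
                                   warm_start = NULL, window = NULL,
                                   dt = 0.01, rtol = 1e-9, atol = 1e-11,
                                   floor = 1e-6) {
  variant <- .check_variant(variant)
  stopifnot(inherits(p, "epi_params"), burn_in > 0)
  if (is.null(window)) window <- if (variant == "free_living") 120 else 60
  y0 <- if (is.null(warm_start)) .default_state(variant) else warm_start
  if (length(y0) != .n_state(variant) || any(y0 <= 0))
    stop("integrate_to_attractor: warm_start must be ", .n_state(variant),
         " strictly positive densities")
  ## coarse burn-in, then the dense window (absolute time continues so that
  ## the phase of forced variants is preserved)
  burn_times <- unique(c(seq(0, burn_in, by = min(burn_in, 50)), burn_in))
  burn <- .integrate_resident(variant, p, tr, y0, burn_times, rtol, atol)
  yb <- burn$states[nrow(burn$states), ]
  win_times <- burn_in + seq(0, window, by = dt)
  win <- .integrate_resident(variant, p, tr, yb, win_times, rtol, atol)
  end_state <- win$states[nrow(win$states), ]
  flags <- list(
    disease_free = end_state[["I"]] < floor,
    host_extinct = end_state[["S"]] < floor
  )
  structure(
    list(variant = variant, p = p, tr = tr,
         times = win$times, states = win$states,
         end_state = end_state, burn_in = burn_in, dt = dt,
         flags = flags, rtol = rtol, atol = atol),
    class = "attractor_run")
}

#' @export
print.attractor_run <- function(x, ...) {
  cat(sprintf("<attractor_run> %s model, burn-in %g, window [%g, %g]\n",
              x$variant, x$burn_in, min(x$times), max(x$times)))
  cat("end state:", paste(sprintf("%s = %.6g", names(x$end_state),
                                  x$end_state), collapse = ", "), "\n")
  if (x$flags$disease_free) cat("flag: disease-free (parasite collapsed)\n")
  if (x$flags$host_extinct) cat("flag: host extinct\n")
  invisible(x)
}

## local maxima with a relative prominence filter; peak times refined by a
## quadratic fit through the three samples around each maximum
.find_peaks <- function(tt, y, prominence = 1e-3) {
  n <- length(y)
  if (n < 3L) return(numeric(0))
  i <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  rng <- diff(range(y))
  if (rng <= 0) return(numeric(0))
  i <- i[y[i] > min(y) + prominence * rng]
  if (!length(i)) return(numeric(0))
  dt <- tt[2L] - tt[1L]
  vapply(i, function(j) {
    d2 <- y[j - 1L] - 2 * y[j] + y[j + 1L]
    if (d2 >= 0) return(tt[j])
    tt[j] + 0.5 * (y[j - 1L] - y[j + 1L]) / d2 * dt
  }, numeric(1))
}

#' Classify the resident attractor and estimate its period
#'
#' Decides whether the post-transient resident dynamics in an
#' [integrate_to_attractor()] run are at an equilibrium or on a limit cycle,
#' and estimates the cycle period. An equilibrium is declared when the
#' relative variation of every state variable over the last 50 time units of
#' the window falls below `equil_tol`. For the externally forced variants the
#' period must be an integer multiple of the forcing period 1; it is found by
#' testing the recurrence of the full state at lags 1..`max_multiplicity`
#' (period-doubling check), which also yields the multiplicity. For
#' intrinsic cycles (`free_living`) the period is the mean interval between
#' successive peaks of the infected-density trajectory, with peak times
#' refined by local quadratic interpolation.
#'
#' @param run an `attractor_run` from [integrate_to_attractor()].
#' @param equil_tol relative-variation threshold declaring an equilibrium.
#' @param recur_tol relative state-recurrence tolerance for the forced-cycle
#'   lag test.
#' @param prominence relative prominence for peak detection.
#' @param cv_tol maximum coefficient of variation of inter-peak intervals
#'   before the trajectory is rejected as having no fixed period (guards
#'   against chaotic or quasi-periodic windows).
#' @param max_multiplicity largest period-doubling multiple tested.
#' @return A list with elements `kind` (`"equilibrium"` or `"cycle"`),
#'   `period` (`NA` for equilibria) and `multiplicity` (forced variants).
#' @export
detect_period <- function(run, equil_tol = 1e-6, recur_tol = 1e-4,
                          prominence = 1e-3, cv_tol = 0.01,
                          max_multiplicity = 4L) {
  stopifnot(inherits(run, "attractor_run"))
  tt <- run$times
  st <- run$states
  ## equilibrium test on the tail of the window
  tail_i <- tt >= max(tt) - min(50, diff(range(tt)) / 2)
  rel_var <- apply(st[tail_i, , drop = FALSE], 2L, function(v)
    diff(range(v)) / max(abs(mean(v)), 1e-12))
  if (max(rel_var) < equil_tol)
    return(list(kind = "equilibrium", period = NA_real_,
                multiplicity = NA_integer_))
  if (.is_forced(run$variant)) {
    ## state recurrence at integer lags of the forcing period
    steps_per_unit <- round(1 / run$dt)
    scale <- pmax(apply(abs(st), 2L, max), 1e-12)
    for (m in seq_len(max_multiplicity)) {
      lag <- m * steps_per_unit
      if (lag >= nrow(st)) break
      head_part <- st[seq_len(nrow(st) - lag), , drop = FALSE]
      lag_part <- st[(lag + 1L):nrow(st), , drop = FALSE]
      err <- max(abs(head_part - lag_part) / rep(scale, each = nrow(head_part)))
      if (err < recur_tol)
        return(list(kind = "cycle", period = as.numeric(m),
                    multiplicity = as.integer(m)))
    }
    stop("detect_period: no fixed period found up to multiplicity ",
         max_multiplicity, " (possible chaos or unconverged transient)")
  }
  ## intrinsic cycle: inter-peak intervals of the infected trajectory
  peaks <- .find_peaks(tt, st[, "I"], prominence)
  if (length(peaks) < 3L)
    stop("detect_period: fewer than 3 infected-density peaks in the window;",
         " window too short for period estimation")
  iv <- diff(peaks)
  if (stats::sd(iv) / mean(iv) > cv_tol)
    stop("detect_period: irregular inter-peak intervals (CV = ",
         signif(stats::sd(iv) / mean(iv), 3),
         "); no fixed period (possible chaos)")
  list(kind = "cycle", period = mean(iv), multiplicity = 1L)
}

#' Canonical one-period cycle representation
#'
#' Resamples the resident attractor onto a uniform grid spanning exactly one
#' period (multiplicity x forcing period for forced variants), starting at a
#' peak of the infected density. The stored phase-0 state and period are what
#' the fitness machinery consumes; the closure gap (relative distance between
#' the first and last state of the resampled period) measures how well the
#' trajectory has converged to the attractor.
#'
#' @param run an `attractor_run`.
#' @param info optional result of [detect_period()]; computed if missing.
#' @param samples_per_period number of grid points over the period.
#' @param closure_tol maximum admissible closure gap; exceeding it signals
#'   that the trajectory has not converged to the attractor.
#' @return An object of class `cycle_attractor` with fields `times` (grid
#'   over `[0, period]`), `states`, `period`, `kind`, `multiplicity`,
#'   `phase0_state`, `t0` (forcing phase of the grid origin) and
#'   `closure_gap`. Equilibria are represented as degenerate constant cycles
#'   of nominal period 1.
#' @export
resample_cycle <- function(run, info = NULL, samples_per_period = 201L,
                           closure_tol = 1e-3) {
  stopifnot(inherits(run, "attractor_run"))
  if (is.null(info)) info <- detect_period(run)
  if (info$kind == "equilibrium") {
    y <- run$end_state
    states <- matrix(rep(y, each = samples_per_period), samples_per_period,
                     dimnames = list(NULL, names(y)))
    return(structure(
      list(variant = run$variant, p = run$p, tr = run$tr,
           times = seq(0, 1, length.out = samples_per_period),
           states = states, period = 1, kind = "equilibrium",
           multiplicity = NA_integer_, phase0_state = y, t0 = 0,
           closure_gap = 0, rtol = run$rtol, atol = run$atol),
      class = "cycle_attractor"))
  }
  period <- info$period
  ## anchor the grid at an I-peak (phase convention); use the sampled state
  ## nearest the refined peak time so state and time stay consistent
  peaks <- .find_peaks(run$times, run$states[, "I"])
  usable <- peaks[peaks + period <= max(run$times)]
  if (!length(usable))
    stop("resample_cycle: window shorter than one period past the first peak")
  anchor <- usable[length(usable)]
  i0 <- which.min(abs(run$times - anchor))
  y0 <- run$states[i0, ]
  t0_abs <- run$times[i0]
  t0 <- if (.is_forced(run$variant)) t0_abs %% 1 else 0
  grid <- seq(0, period, length.out = samples_per_period)
  out <- .integrate_resident(run$variant, run$p, run$tr, y0, t0 + grid,
                             run$rtol, run$atol)
  states <- out$states
  scale <- pmax(abs(y0), 1e-12)
  gap <- max(abs(states[nrow(states), ] - states[1L, ]) / scale)
  if (gap > closure_tol)
    stop("resample_cycle: closure gap ", signif(gap, 3), " exceeds ",
         closure_tol, "; resident not converged to its attractor")
  structure(
    list(variant = run$variant, p = run$p, tr = run$tr,
         times = grid, states = states, period = period, kind = "cycle",
         multiplicity = info$multiplicity, phase0_state = y0, t0 = t0,
         closure_gap = gap, rtol = run$rtol, atol = run$atol),
    class = "cycle_attractor")
}

#' @export
print.cycle_attractor <- function(x, ...) {
  if (x$kind == "equilibrium") {
    cat(sprintf("<cycle_attractor> %s model: equilibrium\n", x$variant))
    cat("state:", paste(sprintf("%s = %.6g", colnames(x$states),
                                x$phase0_state), collapse = ", "), "\n")
  } else {
    cat(sprintf(
      "<cycle_attractor> %s model: limit cycle, period %.6g%s\n",
      x$variant, x$period,
      if (!is.na(x$multiplicity) && x$multiplicity > 1)
        sprintf(" (multiplicity %d)", x$multiplicity) else ""))
    cat(sprintf("closure gap %.3g; %d samples per period\n",
                x$closure_gap, length(x$times)))
  }
  invisible(x)
}

#' Resident attractor in one call
#'
#' Convenience pipeline: [integrate_to_attractor()], [detect_period()] and
#' [resample_cycle()], with the burn-in automatically doubled (up to
#' `max_extend` times, warm-starting each extension from the previous end
#' state) until the cycle closure gap falls below `closure_tol`. Signals a
#' classed condition when the attractor is disease-free or host-extinct, so
#' that grid and sweep code can flag such parameter sets instead of aborting.
#'
#' @inheritParams integrate_to_attractor
#' @param closure_tol required closure gap of the resampled period.
#' @param max_extend maximum number of burn-in doublings.
#' @param samples_per_period grid resolution of the stored cycle.
#' @return A `cycle_attractor`.
#' @export
resident_attractor <- function(variant, p, tr = NULL, burn_in = 500,
                               warm_start = NULL, closure_tol = 1e-5,
                               max_extend = 3L, samples_per_period = 201L,
                               dt = 0.01, rtol = 1e-9, atol = 1e-11) {
  variant <- .check_variant(variant)
  for (try in 0:max_extend) {
    run <- integrate_to_attractor(variant, p, tr, burn_in = burn_in,
                                  warm_start = warm_start, dt = dt,
                                  rtol = rtol, atol = atol)
    if (run$flags$disease_free || run$flags$host_extinct)
      stop(.disease_free_condition(paste0(
        "resident attractor is ",
        if (run$flags$host_extinct) "host-extinct" else "disease-free",
        " at beta = ", signif(p$beta, 6))))
    cyc <- resample_cycle(run, samples_per_period = samples_per_period,
                          closure_tol = Inf)
    if (cyc$closure_gap <= closure_tol) return(cyc)
    warm_start <- run$end_state
    burn_in <- burn_in * 2
  }
  stop("resident_attractor: closure gap ", signif(cyc$closure_gap, 3),
       " still above ", closure_tol, " after ", max_extend,
       " burn-in extensions")
}

#' Export a sampled cycle as CSV
#'
#' Writes the canonical one-period sample of a [resident_attractor()] as a
#' plain CSV with columns `t`, `S`, `I` (and `P` for the free-living model).
#'
#' @param cycle a `cycle_attractor`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
export_cycle_csv <- function(cycle, path) {
  stopifnot(inherits(cycle, "cycle_attractor"))
  df <- data.frame(t = cycle$times, cycle$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
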