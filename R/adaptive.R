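## Adaptive dynamics on top of the invasion-fitness machinery: selection
## gradients, pairwise invasion plots, location and classification of
## singular strategies, and continuation of singular strategies across
## parameter sweeps.

## gradient + the attractor it was computed on (so loops can warm-start and
## reuse); returns list(gradient, attractor)
.gradient_on_attractor <- function(variant, p, tr, beta_r, h,
                                   warm_start = NULL, ...) {
  p$beta <- beta_r
  att <- resident_attractor(variant, p, tr, warm_start = warm_start, ...)
  up <- .fitness_value(variant, p, tr, beta_r + h, beta_r, att)
  dn <- .fitness_value(variant, p, tr, beta_r - h, beta_r, att)
  list(gradient = (up - dn) / (2 * h), attractor = att)
}

#' Local selection gradient
#'
#' Central finite difference of the invasion fitness in the mutant trait at
#' the resident value: \eqn{(s(\beta+h, \beta) - s(\beta-h, \beta))/2h}.
#' Positive: selection for higher transmission (lower defence); negative:
#' selection for lower transmission. Both fitness evaluations share one
#' resident attractor.
#'
#' @inheritParams invasion_fitness
#' @param h finite-difference step in the trait (absolute).
#' @param ... passed to [resident_attractor()] when `attractor` is missing.
#' @return The selection gradient (a single number).
#' @export
selection_gradient <- function(variant, p, tr = NULL, beta_r, h = 1e-3,
                               attractor = NULL, ...) {
  variant <- .check_variant(variant)
  stopifnot(h > 0)
  if (!is.null(attractor)) {
    p$beta <- beta_r
    up <- .fitness_value(variant, p, tr, beta_r + h, beta_r, attractor)
    dn <- .fitness_value(variant, p, tr, beta_r - h, beta_r, attractor)
    return((up - dn) / (2 * h))
  }
  .gradient_on_attractor(variant, p, tr, beta_r, h, ...)$gradient
}

#' Pairwise invasion plot
#'
#' Sign of the invasion fitness over an `n` x `n` grid of (resident, mutant)
#' trait pairs. Resident attractors are recomputed per column,
#' warm-started from the previous column's attractor. Columns whose
#' resident is disease-free (subcritical) are flagged and filled with `NA`
#' rather than silently zeroed.
#'
#' @inheritParams invasion_fitness
#' @param trait_range length-2 numeric range of the trait grid.
#' @param n grid size (at least 20).
#' @param zero_tolerance fitness magnitudes below this are recorded as
#'   neutral (sign 0).
#' @param ... passed to [resident_attractor()].
#' @return An object of class `pip_grid` with `trait_values`, the `fitness`
#'   and `sign` matrices (rows: mutants, columns: residents), and the
#'   per-column `flagged` vector.
#' @export
pairwise_invasion_plot <- function(variant, p, tr = NULL, trait_range,
                                   n = 41L, zero_tolerance = 1e-5, ...) {
  variant <- .check_variant(variant)
  stopifnot(length(trait_range) == 2L, n >= 20L)
  bv <- seq(trait_range[1L], trait_range[2L], length.out = n)
  fit <- matrix(NA_real_, n, n, dimnames = list(mutant = NULL,
                                                resident = NULL))
  flagged <- logical(n)
  warm <- NULL
  for (j in seq_len(n)) {
    p$beta <- bv[j]
    att <- tryCatch(
      resident_attractor(variant, p, tr, warm_start = warm, ...),
      floquetad_disease_free = function(e) NULL)
    if (is.null(att)) {
      flagged[j] <- TRUE
      warm <- NULL
      next
    }
    warm <- att$phase0_state
    for (i in seq_len(n))
      fit[i, j] <- .fitness_value(variant, p, tr, bv[i], bv[j], att)
  }
  sgn <- sign(fit)
  sgn[abs(fit) < zero_tolerance] <- 0
  structure(list(trait_values = bv, fitness = fit, sign_matrix = sgn,
                 zero_tolerance = zero_tolerance, flagged = flagged,
                 variant = variant, p = p, tr = tr),
            class = "pip_grid")
}

#' @export
print.pip_grid <- function(x, ...) {
  n <- length(x$trait_values)
  cat(sprintf("<pip_grid> %s model, %d x %d grid over [%g, %g]\n",
              x$variant, n, n, min(x$trait_values), max(x$trait_values)))
  if (any(x$flagged))
    cat("disease-free resident columns:",
        paste(signif(x$trait_values[x$flagged], 4), collapse = ", "), "\n")
  ok <- x$sign_matrix[!is.na(x$sign_matrix)]
  cat(sprintf("invadable pairs: %d / %d\n", sum(ok > 0), length(ok)))
  invisible(x)
}

#' @export
as.data.frame.pip_grid <- function(x, ...) {
  n <- length(x$trait_values)
  data.frame(beta_r = rep(x$trait_values, each = n),
             beta_m = rep(x$trait_values, n),
             fitness = as.vector(x$fitness),
             sign = as.vector(x$sign_matrix))
}

.singular_obj <- function(beta_star, gradient = NA_real_,
                          converg_stable = NA, evol_stable = NA,
                          label = NA_character_, es_curvature = NA_real_,
                          cs_slope = NA_real_, h_used = NA_real_,
                          kind = NA_character_, period = NA_real_,
                          multiplicity = NA_integer_) {
  structure(list(beta_star = beta_star, gradient = gradient,
                 converg_stable = converg_stable, evol_stable = evol_stable,
                 label = label, es_curvature = es_curvature,
                 cs_slope = cs_slope, h_used = h_used, kind = kind,
                 period = period, multiplicity = multiplicity),
            class = "singular_strategy")
}

#' @export
print.singular_strategy <- function(x, ...) {
  cat(sprintf("<singular_strategy> beta* = %.6g", x$beta_star))
  if (!is.na(x$label)) {
    cat(sprintf("  [%s]\n", x$label))
    cat(sprintf("  evolutionarily %sstable (curvature %.4g, step %g)\n",
                if (isTRUE(x$evol_stable)) "" else "un", x$es_curvature,
                x$h_used))
    cat(sprintf("  convergence %sstable (gradient slope %.4g)\n",
                if (isTRUE(x$converg_stable)) "" else "un", x$cs_slope))
  } else cat("  (not yet classified)\n")
  invisible(x)
}

## gradient evaluation that tolerates disease-free residents (returns NA)
.safe_gradient <- function(variant, p, tr, beta_r, h, warm, ...) {
  tryCatch(
    .gradient_on_attractor(variant, p, tr, beta_r, h, warm_start = warm, ...),
    floquetad_disease_free = function(e) list(gradient = NA_real_,
                                              attractor = NULL))
}

#' Locate an evolutionarily singular strategy
#'
#' Finds a zero of the selection gradient by bisection on its sign inside
#' `bracket`. If the gradient does not change sign between the bracket ends
#' (or a bracket end has a disease-free resident), the bracket is first
#' scanned on a coarse grid for a sign change between adjacent valid points.
#'
#' @inheritParams selection_gradient
#' @param bracket length-2 trait interval believed to contain the singular
#'   point.
#' @param tol bracket width at which bisection stops (location tolerance).
#' @param scan_points number of points in the fallback bracketing scan.
#' @param ... passed to [resident_attractor()].
#' @return A `singular_strategy` (location and gradient only; see
#'   [classify_singular_strategy()] for the stability flags). The attractor
#'   at the singular point is attached as attribute `"attractor"`.
#' @export
find_singular_strategy <- function(variant, p, tr = NULL, bracket,
                                   tol = 1e-4, h = 1e-3, scan_points = 9L,
                                   ...) {
  variant <- .check_variant(variant)
  stopifnot(length(bracket) == 2L, diff(bracket) > 0, tol > 0)
  lo <- bracket[1L]; hi <- bracket[2L]
  glo <- .safe_gradient(variant, p, tr, lo, h, NULL, ...)
  ghi <- .safe_gradient(variant, p, tr, hi, h,
                        glo$attractor$phase0_state, ...)
  if (is.na(glo$gradient) || is.na(ghi$gradient) ||
      sign(glo$gradient) == sign(ghi$gradient)) {
    ## scan for a valid sign-change sub-bracket, refining the grid when the
    ## endemic window is narrower than the scan spacing (residents near the
    ## R0 = 1 boundary are disease-free and give no gradient)
    chg <- integer(0)
    warm <- NULL
    np <- scan_points
    for (round in 1:3) {
      grid <- seq(lo, hi, length.out = np)
      gv <- rep(NA_real_, np)
      for (i in seq_along(grid)) {
        gi <- .safe_gradient(variant, p, tr, grid[i], h, warm, ...)
        gv[i] <- gi$gradient
        if (!is.null(gi$attractor)) warm <- gi$attractor$phase0_state
      }
      ok <- which(!is.na(gv))
      chg <- ok[which(diff(sign(gv[ok])) != 0 & diff(ok) == 1)]
      if (length(chg)) break
      np <- 4L * (np - 1L) + 1L
    }
    if (!length(chg))
      stop("find_singular_strategy: no interior singular point ",
           "(selection gradient does not change sign in the bracket)")
    lo <- grid[chg[1L]]; hi <- grid[chg[1L] + 1L]
    glo <- .safe_gradient(variant, p, tr, lo, h, warm, ...)
  }
  warm <- glo$attractor$phase0_state
  att <- glo$attractor
  g_mid <- glo$gradient
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- .gradient_on_attractor(variant, p, tr, mid, h,
                                 warm_start = warm, ...)
    warm <- gm$attractor$phase0_state
    att <- gm$attractor
    g_mid <- gm$gradient
    if (sign(gm$gradient) == sign(glo$gradient)) {
      lo <- mid
      glo$gradient <- gm$gradient
    } else {
      hi <- mid
    }
  }
  beta_star <- (lo + hi) / 2
  out <- .singular_obj(beta_star, gradient = g_mid,
                       kind = att$kind, period = att$period,
                       multiplicity = att$multiplicity)
  attr(out, "attractor") <- att
  out
}

#' Classify a singular strategy
#'
#' Second-order finite-difference classification at a located singular
#' trait value: evolutionary stability from the curvature of the invasion
#' fitness in the mutant trait at the singular resident
#' (\eqn{\partial^2 s/\partial\beta_m^2 < 0}: uninvadable), convergence
#' stability from the slope of the selection gradient across resident values
#' (negative: attracting). The four combinations give a continuously stable
#' strategy (CSS), an evolutionary branching point, a repeller, or a
#' "garden of Eden" (uninvadable but unattainable) point. A curvature whose
#' magnitude falls below `noise_floor` is labelled `indeterminate` rather
#' than guessed.
#'
#' @inheritParams selection_gradient
#' @param beta_star singular trait value (from [find_singular_strategy()]).
#' @param h finite-difference step for the curvature and gradient slope.
#' @param grad_h step used inside the nested selection gradients.
#' @param noise_floor curvature magnitude below which the evolutionary
#'   stability call is refused.
#' @param ... passed to [resident_attractor()].
#' @return A `singular_strategy` with stability flags, label and the
#'   curvatures (and step sizes) used.
#' @export
classify_singular_strategy <- function(variant, p, tr = NULL, beta_star,
                                       h = 5e-3, grad_h = 1e-3,
                                       noise_floor = 1e-3, ...) {
  variant <- .check_variant(variant)
  g0 <- .gradient_on_attractor(variant, p, tr, beta_star, grad_h, ...)
  att <- g0$attractor
  p$beta <- beta_star
  s_up <- .fitness_value(variant, p, tr, beta_star + h, beta_star, att)
  s_dn <- .fitness_value(variant, p, tr, beta_star - h, beta_star, att)
  s_0 <- .fitness_value(variant, p, tr, beta_star, beta_star, att)
  es_curv <- (s_up - 2 * s_0 + s_dn) / h^2
  g_up <- .gradient_on_attractor(variant, p, tr, beta_star + h, grad_h,
                                 warm_start = att$phase0_state, ...)$gradient
  g_dn <- .gradient_on_attractor(variant, p, tr, beta_star - h, grad_h,
                                 warm_start = att$phase0_state, ...)$gradient
  cs_slope <- (g_up - g_dn) / (2 * h)
  evol_stable <- es_curv < 0
  converg_stable <- cs_slope < 0
  label <- if (abs(es_curv) < noise_floor) {
    "indeterminate"
  } else if (converg_stable && evol_stable) {
    "CSS"
  } else if (converg_stable && !evol_stable) {
    "branching"
  } else if (!converg_stable && evol_stable) {
    "garden_of_eden"
  } else {
    "repeller"
  }
  .singular_obj(beta_star, gradient = g0$gradient,
                converg_stable = converg_stable, evol_stable = evol_stable,
                label = label, es_curvature = es_curv, cs_slope = cs_slope,
                h_used = h, kind = att$kind, period = att$period,
                multiplicity = att$multiplicity)
}

#' Track a singular strategy across a parameter sweep
#'
#' Locates the singular trait value for each value of a swept
#' epidemiological parameter, by continuation: each located \eqn{\beta^*}
#' seeds a narrow bracket around the next parameter value (expanded, up to
#' the full bracket, if the gradient does not change sign there). The
#' attractor kind, period and multiplicity at each singular point are
#' recorded alongside. Rows where the singular strategy is lost are flagged
#' `"lost"` and the sweep continues from the full bracket.
#'
#' @inheritParams find_singular_strategy
#' @param param name of the [epi_params()] field to sweep.
#' @param values ordered vector of parameter values.
#' @param bracket full trait bracket valid at the first value.
#' @param ... passed to [resident_attractor()].
#' @return A data frame (class `css_sweep`) with columns `param`, `value`,
#'   `beta_star`, `kind`, `period`, `multiplicity`, `status`.
#' @export
css_parameter_sweep <- function(variant, p, tr = NULL, param, values,
                                bracket, tol = 1e-4, h = 1e-3, ...) {
  variant <- .check_variant(variant)
  if (!param %in% names(p))
    stop("css_parameter_sweep: unknown parameter '", param, "'")
  rows <- vector("list", length(values))
  prev <- NA_real_
  width0 <- 0.15 * diff(bracket)
  for (i in seq_along(values)) {
    p[[param]] <- values[i]
    sing <- NULL
    if (!is.na(prev)) {
      w <- width0
      while (is.null(sing) && w <= diff(bracket)) {
        br <- c(max(bracket[1L], prev - w), min(bracket[2L], prev + w))
        sing <- tryCatch(
          find_singular_strategy(variant, p, tr, br, tol = tol, h = h, ...),
          error = function(e) NULL)
        w <- w * 2
      }
    }
    if (is.null(sing))
      sing <- tryCatch(
        find_singular_strategy(variant, p, tr, bracket, tol = tol, h = h,
                               ...),
        error = function(e) NULL)
    if (is.null(sing)) {
      rows[[i]] <- data.frame(param = param, value = values[i],
                              beta_star = NA_real_, kind = NA_character_,
                              period = NA_real_,
                              multiplicity = NA_integer_, status = "lost")
      prev <- NA_real_
    } else {
      rows[[i]] <- data.frame(param = param, value = values[i],
                              beta_star = sing$beta_star, kind = sing$kind,
                              period = sing$period,
                              multiplicity = sing$multiplicity,
                              status = "ok")
      prev <- sing$beta_star
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("css_sweep", class(out))
  out
}
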