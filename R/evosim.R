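## Direct multi-strain simulation of the evolutionary process: an
## independent check on the invasion analysis. A lattice of host strains
## shares the crowding term (and, for the free-living variant, the parasite
## pool); every epoch, sub-threshold strains go extinct and a mutant
## adjacent to the dominant strain is introduced at low density.

## state layout: c(S[1..n], I[1..n]) plus a trailing shared P for the
## free-living variant
.ms_unpack <- function(variant, state, n) {
  list(S = state[seq_len(n)], I = state[n + seq_len(n)],
       P = if (variant == "free_living") state[2L * n + 1L] else NULL)
}

.ms_rhs <- function(variant, p, t, state, a_values, beta_values) {
  n <- length(beta_values)
  S <- state[seq_len(n)]
  I <- state[n + seq_len(n)]
  q <- .q_at(variant, p, t)
  af <- .births_forcing(variant, p, t)
  k <- p$b + p$alpha + p$gamma
  N <- sum(S) + sum(I)
  FF <- if (variant == "free_living") state[2L * n + 1L] else sum(I)
  inf <- beta_values * S * FF
  dS <- (a_values * af - q * N) * S - p$b * S - inf + p$gamma * I
  dI <- inf - k * I
  if (variant == "free_living") {
    dP <- p$theta * sum(I) - p$decay * state[2L * n + 1L]
    c(dS, dI, dP)
  } else {
    c(dS, dI)
  }
}

#' Multi-strain right-hand side
#'
#' Natural multi-strain extension of [resident_rhs()]: each host strain `i`
#' carries its own trait \eqn{\beta_i} (and birth rate \eqn{a(\beta_i)}
#' under the trade-off), while crowding acts through the shared total
#' density \eqn{\sum_j (S_j + I_j)}, infection through the shared infected
#' pool \eqn{\sum_j I_j} (or the shared free-living pool `P`, fed by
#' \eqn{\theta \sum_j I_j}). With a single extant strain this reduces
#' exactly to [resident_rhs()].
#'
#' @inheritParams resident_rhs
#' @param state strain densities `c(S[1..n], I[1..n])`, plus a trailing
#'   shared `P` for the free-living variant.
#' @param beta_values trait value of each strain on the lattice.
#' @return Vector of time derivatives, same layout as `state`.
#' @export
multistrain_rhs <- function(variant, p, tr = NULL, t, state, beta_values) {
  variant <- .check_variant(variant)
  stopifnot(inherits(p, "epi_params"))
  n <- length(beta_values)
  want <- 2L * n + (variant == "free_living")
  if (length(state) != want)
    stop("multistrain_rhs: expected ", want, " state entries for ", n,
         " strains, got ", length(state))
  if (any(state[seq_len(2L * n)] < 0))
    stop("multistrain_rhs: strain densities must be non-negative")
  a_values <- if (is.null(tr)) rep(p$a0, n) else birth_rate(tr, beta_values)
  .ms_rhs(variant, p, t, state, a_values, beta_values)
}

#' Simulate the evolutionary process on a trait lattice
#'
#' Multi-strain trait-substitution simulation: starting from a single
#' resident strain, the ecological dynamics run for `epoch` time units;
#' strains whose total density falls below `extinction_threshold` are then
#' removed, the dominant strain is identified by its total density averaged
#' over the final forcing period of the epoch (a point sample can
#' accidentally cull a fit strain caught at a cycle trough), and one mutant
#' adjacent to the dominant strain on the lattice is seeded at
#' `mutant_density` (direction random; at a lattice edge the single interior
#' neighbour is used). Repeating for `n_steps` mutation steps traces the
#' evolutionary trajectory.
#'
#' @inheritParams resident_rhs
#' @param trait_range trait lattice range (ignored if `beta_values` given).
#' @param n_strains lattice size.
#' @param beta_values explicit trait lattice (overrides `trait_range`).
#' @param init_beta starting trait (snapped to the nearest lattice point).
#' @param n_steps number of mutation steps (epochs).
#' @param epoch ecological time between mutation events; for forced
#'   variants keep this an integer multiple of the forcing period so that
#'   extinction checks always happen at the same cycle phase.
#' @param extinction_threshold total strain density below which a strain is
#'   set extinct.
#' @param mutant_density density at which a new mutant is seeded.
#' @param seed RNG seed for the mutation directions (reproducibility).
#' @param rtol,atol solver tolerances for the ecological epochs.
#' @param sample_dt sampling interval for the final-period density average.
#' @return An object of class `evo_trajectory`: `$records` (long data frame
#'   `step`, `beta`, `density` of extant strains after each epoch),
#'   `$dominant` (per-step dominant trait), `$beta_values`, and a
#'   `$terminated` flag set if all strains went extinct.
#' @export
evolve <- function(variant, p, tr = NULL, trait_range = c(0.05, 0.5),
                   n_strains = 61L, beta_values = NULL, init_beta,
                   n_steps = 100L, epoch = 50, extinction_threshold = 1e-5,
                   mutant_density = 1e-3, seed = NULL, rtol = 1e-6,
                   atol = 1e-8, sample_dt = 0.02) {
  variant <- .check_variant(variant)
  stopifnot(inherits(p, "epi_params"), epoch > 0, n_steps >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta_values))
    beta_values <- seq(trait_range[1L], trait_range[2L],
                       length.out = n_strains)
  n <- length(beta_values)
  a_values <- if (is.null(tr)) rep(p$a0, n) else birth_rate(tr, beta_values)
  func <- function(t, y, parms)
    list(.ms_rhs(variant, p, t, y, a_values, beta_values))
  i0 <- which.min(abs(beta_values - init_beta))
  y <- numeric(2L * n + (variant == "free_living"))
  y[i0] <- 1; y[n + i0] <- 1
  if (variant == "free_living") y[2L * n + 1L] <- 1
  records <- vector("list", n_steps)
  dominant <- rep(NA_real_, n_steps)
  terminated <- FALSE
  t_abs <- 0
  avg_window <- min(1, epoch)
  for (step in seq_len(n_steps)) {
    ## bulk of the epoch, then a densely sampled final forcing period
    out <- deSolve::ode(y, t_abs + c(0, epoch - avg_window), func, NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 500000)
    y <- pmax(out[nrow(out), -1L], 0)
    fine <- deSolve::ode(y, t_abs + seq(epoch - avg_window, epoch,
                                        by = sample_dt),
                         func, NULL, method = "lsoda", rtol = rtol,
                         atol = atol, maxsteps = 500000)
    avg <- colMeans(fine[, -1L, drop = FALSE])
    y <- pmax(fine[nrow(fine), -1L], 0)
    t_abs <- t_abs + epoch
    tot_end <- y[seq_len(n)] + y[n + seq_len(n)]
    tot_avg <- avg[seq_len(n)] + avg[n + seq_len(n)]
    ## extinction, then mutation adjacent to the period-averaged dominant
    extinct <- tot_end < extinction_threshold
    y[seq_len(n)][extinct] <- 0
    y[n + seq_len(n)][extinct] <- 0
    tot_avg[extinct] <- 0
    if (all(tot_avg == 0)) {
      terminated <- TRUE
      records[[step]] <- data.frame(step = step, beta = numeric(0),
                                    density = numeric(0))
      break
    }
    dom <- which.max(tot_avg)
    dominant[step] <- beta_values[dom]
    extant <- which(tot_avg > 0)
    records[[step]] <- data.frame(step = step, beta = beta_values[extant],
                                  density = tot_avg[extant])
    if (n > 1L) {
      dir <- if (dom == 1L) 1L else if (dom == n) -1L else
        sample(c(-1L, 1L), 1L)
      y[dom + dir] <- y[dom + dir] + mutant_density
    }
  }
  structure(list(records = do.call(rbind, records),
                 dominant = data.frame(step = seq_len(n_steps),
                                       beta = dominant),
                 beta_values = beta_values, variant = variant, p = p,
                 tr = tr, n_steps = n_steps, epoch = epoch,
                 terminated = terminated, final_state = y),
            class = "evo_trajectory")
}

#' @export
print.evo_trajectory <- function(x, ...) {
  cat(sprintf("<evo_trajectory> %s model, %d mutation steps of %g time units\n",
              x$variant, x$n_steps, x$epoch))
  if (x$terminated) cat("terminated early: all strains extinct\n")
  dm <- x$dominant$beta[!is.na(x$dominant$beta)]
  if (length(dm))
    cat(sprintf("dominant trait: %.4g (start) -> %.4g (end)\n",
                dm[1L], dm[length(dm)]))
  invisible(x)
}

#' @export
as.data.frame.evo_trajectory <- function(x, ...) x$records
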