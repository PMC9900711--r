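---
title: "Invasion analysis on ecological limit cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invasion analysis on ecological limit cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most eco-evolutionary invasion analyses assume the resident population sits
at a stable equilibrium, so that the invasion fitness of a rare mutant is a
single number: the dominant eigenvalue of the mutant's linearized dynamics
at that equilibrium. Many host–parasite systems, however, settle on limit
cycles — either because the environment forces them (seasonality in
competition or reproduction) or because the epidemiological structure
itself generates oscillations (free-living parasite stages). On a cycle,
mutant densities rise and fall within a period, so neither a point estimate
of density nor of its slope says anything about long-run invasion success.
The fitness that does is the dominant **Floquet exponent** of the mutant's
linear time-periodic subsystem, and this package is a toolkit for
computing it and building a full adaptive-dynamics analysis on top.

## Models

All variants share an SIS skeleton for susceptible ($S$) and infected
($I$) host densities:

$$\frac{dS}{dt} = (a - q(S+I))S - bS - \beta S F + \gamma I, \qquad
  \frac{dI}{dt} = \beta S F - (b+\alpha+\gamma) I,$$

with logistic-style crowding $q$, natural mortality $b$, virulence
$\alpha$, recovery $\gamma$ and transmission governed by the host trait
$\beta$. The infection partner $F$ and the source of fluctuations
distinguish the variants:

* `baseline` — $F = I$, constant parameters. The endemic equilibrium is
  closed-form: $S^* = (b+\alpha+\gamma)/\beta$ and
  $I^* = (a - qS^* - b)S^*/((q+\beta)S^* - \gamma)$, valid when
  $R_0 = \beta S_{dfe}/(b+\alpha+\gamma) > 1$ with
  $S_{dfe} = (a-b)/q$. (Note the $-\gamma$ in the $I^*$ denominator: it is
  what makes $I^*$ an exact fixed point of the equations above, which the
  test suite verifies directly, and it is the value consistent with the
  trade-off calibration below.)
* `seasonal` — competition is forced, $q(t) = q_0(1 + \delta\sin 2\pi t)$
  with amplitude $\delta \in [0,1]$ and period exactly one year.
* `seasonal_births` — the birth rate is forced instead,
  $a(\beta, t) = a(\beta)(1+\delta\sin 2\pi t)$; this is the classic
  illustrative case and reuses all of the same machinery.
* `free_living` — infection through free-living stages $P$ shed at rate
  $\theta$ by infected hosts and decaying at rate `decay`:
  $F = P$, $dP/dt = \theta I - \mathrm{decay}\,P$. Cycles here are
  intrinsic, so their period is an emergent, generally non-integer number.

The evolving trait is the host's transmission coefficient $\beta$ (lower
$\beta$ = better avoidance of infection), paid for through reproduction:
$a(\beta) = a_{ref} - (\tau_1^2/\tau_2)\{1 - \exp((\beta-\beta_{ref})
\tau_2/\tau_1)\}$, so that $a$, $a'$ and $a''$ at the reference trait are
exactly $a_{ref}$, $\tau_1$ and $\tau_2$. Negative $\tau_2$ gives a
decelerating cost (favouring a CSS), positive $\tau_2$ an accelerating one
(allowing branching). The degenerate linear case $\tau_2 = 0$ is rejected
rather than special-cased.

### Calibrating the trade-off gradient

At the baseline endemic equilibrium the selection gradient of the mutant's
dominant eigenvalue vanishes exactly when
$a'(\beta^*) = I^*(b+\alpha)/(b+\alpha+\gamma)$. `calibrate_tau1()` uses
this closed form to choose $\tau_1$ so that a given reference trait is
singular in the unforced model; with the Figure-2 defaults
($q_0 = 0.5$) it returns $1.579 \approx 1.58$, and the located singular
strategy then sits at $\beta^* = 0.200$ to within the bisection tolerance.
Amplitude sweeps at different competition levels (the `fig3a` preset)
recalibrate $\tau_1$ per panel this way, so that every panel starts from
the same singular trait at zero amplitude and the sweep isolates the
effect of the forcing; without recalibration the weak-competition panel
has no interior singular strategy at all in the plotted trait range.

## The Floquet pipeline

For a resident with trait $\beta$ the pipeline is:

1. **Attractor.** `integrate_to_attractor()` runs the resident past its
   transient (default burn-in 500 time units, doubled automatically — up
   to three times, warm-starting from the previous end state — until the
   resampled cycle closes to within $10^{-5}$ relative). The free-living
   variant is integrated in log coordinates ($X=\ln S$ etc., `log_rhs()`),
   which removes the stiffness caused by densities traversing several
   orders of magnitude within a cycle; the two representations are
   verified against each other in the tests.
2. **Period.** `detect_period()` first tests for an equilibrium (relative
   variation of every state below $10^{-6}$ over the last 50 time units).
   For forced variants the period must be an integer multiple of the
   forcing period, so it is found by testing recurrence of the full state
   vector at lags $1,\dots,4$ years (relative tolerance $10^{-4}$) — this
   yields the period-doubling multiplicity directly and is more robust
   than comparing peak heights. For intrinsic cycles the period is the
   mean spacing of infected-density peaks (local maxima with relative
   prominence $\ge 10^{-3}$, peak times refined by a quadratic fit through
   the three neighbouring samples); intervals with a coefficient of
   variation above $10^{-2}$ are rejected as "no fixed period" rather
   than averaged, as a guard against chaotic or unconverged windows.
3. **Monodromy.** `monodromy_matrix()` co-integrates the resident (from
   the stored phase-0 state — the stored cycle supplies only an initial
   condition and the period, avoiding interpolation error in stiff
   regions) together with two copies of the linear mutant subsystem
   $(S_m, I_m)$ started from $[1,0]$ and $[0,1]$, over exactly one period
   (multiplicity × forcing period if doubled). The end states form the
   matrix $C$; its eigenvalues are the Floquet multipliers
   $\rho_i = e^{\mu_i T}$.
4. **Fitness.** The invasion fitness is $\mu = \ln(\rho_{\max})/T$. The
   $1/T$ normalization does not affect signs but makes exponents
   comparable across attractors with different periods (essential for the
   free-living sweeps, where the period itself changes along the sweep).

Cycles are stored starting at an infected-density peak. This phase
convention is arbitrary — the exponent is invariant to the starting phase,
which the test suite checks to $10^{-6}$ — but it makes warm-started
attractors comparable across parameter values. Similarly, any
non-singular pair of mutant initial conditions gives the same multipliers
($C$ is recovered as $Y(T)M^{-1}$ for an initial basis $M$); the default
unit vectors are used purely for convenience.

### Special cases and cross-checks

* **Equilibrium residents.** `invasion_fitness()` dispatches equilibrium
  attractors to the dominant eigenvalue of the constant mutant Jacobian
  (method `"eigen"`), which is the exact zero-amplitude limit of the
  Floquet exponent — the tests require agreement to $10^{-4}$ between the
  Floquet route at $\delta = 10^{-6}$ and the eigenvalue route at
  $\delta = 0$. The closed-form next-generation expression
  (`ngm_fitness_equilibrium()`) is kept as a separate function: it is a
  *per-generation* quantity (expected offspring minus one), sign-equivalent
  to the eigenvalue but on a different scale, so it serves as an
  independent sign oracle and as the fast route for the non-seasonal
  singular-strategy location, never as a stand-in for the per-time growth
  rate.
* **No recovery.** With $\gamma = 0$ the mutant is unstructured and the
  fitness is the period-average of its per-capita growth rate
  (`average_growth_fitness()`, computed by co-integrating an auxiliary
  quadrature state, so its accuracy matches the solver tolerance). For a
  scalar linear system this equals the Floquet exponent exactly; the two
  independent routes agree to $10^{-5}$ in the tests.
* **Neutrality.** A mutant identical to the resident rides the resident
  cycle, so its dominant multiplier is exactly 1 when the resident is
  exactly on the attractor. The measured self-invasion fitness (order
  $10^{-8}$ across presets) is therefore an end-to-end health check of
  attractor convergence, period estimation and monodromy integration
  combined; the tests enforce $|s(\beta,\beta)| < 10^{-4}$.

## Adaptive dynamics

The selection gradient is a central finite difference of the invasion
fitness in the mutant trait ($h = 10^{-3}$ in absolute trait units, chosen
above the integration noise floor and verified by a step-halving
robustness check); both fitness evaluations share one resident attractor.
`find_singular_strategy()` bisects the gradient's sign to a location
tolerance of $10^{-4}$, scanning the bracket on a coarse grid first when
an endpoint is subcritical (disease-free residents are signalled as a
classed condition, never silently zeroed). Classification uses local
curvatures with a wider step ($h = 5\times10^{-3}$, since second
differences amplify noise): evolutionary stability from
$\partial^2 s/\partial\beta_m^2 < 0$ at the singular resident, convergence
stability from the slope of the gradient across residents. Curvature
magnitudes below $10^{-3}$ are labelled `indeterminate` rather than
guessed. `css_parameter_sweep()` tracks a singular strategy across a
parameter by continuation (the previous $\beta^*$ seeds a narrow bracket,
expanded geometrically on failure; rows where the root is genuinely lost
are flagged and the sweep continues), recording the attractor kind,
period and multiplicity alongside — on the free-living sweeps this is what
exposes the change of CSS trend at the cycle/equilibrium boundary.

Pairwise invasion plots (`pairwise_invasion_plot()`, default 41×41 but any
$n \ge 20$) recompute the resident attractor per column, warm-started
column to column; fitness magnitudes below $10^{-5}$ are recorded as
neutral, which keeps the diagonal exactly neutral in the sign matrix.

## The multi-strain simulator

`evolve()` is the independent, assumption-light check on the invasion
analysis: a lattice of 61 strains spanning the trait range, sharing
crowding (and the free-living pool), integrated in ecological epochs of
50 time units — an integer multiple of the forcing period, so extinction
checks always land at the same cycle phase. After each epoch, strains
below a total density of $10^{-5}$ go extinct and one mutant adjacent to
the dominant strain is seeded at $10^{-3}$ (direction random under the
run's seed; at a lattice edge the single interior neighbour is used).
Dominance is judged by total strain density *averaged over the final
forcing period* of the epoch, not a point value: on a cycle, a point
sample can catch the fittest strain in a trough and cull it, which is the
known failure mode of naive multi-strain simulations and the reason the
extinction threshold is set well below typical trough densities. The
trait substitution sequence is slow by construction — a fitter neighbour
must grow from $10^{-3}$ to dominance before the next substitution — so
the CSS cross-validation run uses 500 mutation steps, by which point the
dominant trait has settled within two lattice steps of the analytically
located CSS and stays there.

What the simulator does *not* emulate: demographic stochasticity (it is a
deterministic ODE between mutation events), standing genetic variation
(one mutant per epoch, adjacent steps only), and mutation-limited
timescale separation failures. Passing the cross-validation therefore
confirms the invasion analysis within the adaptive-dynamics assumptions,
not beyond them.

## Numerical choices

* Solver: `deSolve::lsoda` everywhere (automatic stiff/non-stiff
  switching), relative tolerance $10^{-9}$ and absolute $10^{-11}$ for
  attractor and monodromy work; the multi-strain simulator uses
  $10^{-6}/10^{-8}$ (it needs ordering of strain densities, not
  eigenvalue-grade accuracy).
* Observation windows: 60 time units (120 for the free-living variant,
  whose ≈10-unit period is not known in advance) sampled at
  $dt = 0.01$, giving ≥ 1000 samples per period.
* Default initial condition $(S, I[, P]) = (1, 1[, 1])$; warm-start
  independence of the attractor (kind, period, and the phase-aligned
  cycle itself) is a tested property, so the choice is immaterial.
* Degenerate inputs: equilibria are carried as constant "cycles" of
  nominal period 1, so every downstream consumer works unchanged; a
  zero-length period returns the identity monodromy matrix and zero
  exponent.
* Complex dominant multipliers (which would violate the positivity
  structure of these systems) trigger a warning and fall back to the
  modulus; they have not been observed at any shipped preset.

## Worked-example problem sizes

The shipped analyses use: burn-in 500 (extended automatically when
needed); 201 samples per stored period; 20×20 fitness grids for the
sign-agreement checks; amplitude sweeps over $\delta \in \{0, 0.3, 0.6,
0.9\}$ at $q_0 \in \{0.1, 0.5\}$; and a 500-epoch, 61-strain evolutionary
simulation for the CSS cross-validation. These sizes are the package's
own choices for the worked examples; all are arguments, not constants.

## Known limitations

* Chaotic or quasi-periodic attractors are out of scope: the period
  detector refuses them (interval CV guard) instead of producing a
  meaningless monodromy matrix.
* The mutant subsystem is two-dimensional by the rare-mutant argument;
  mutant shedding into the shared free-living pool is neglected at
  invasion. This is exact in the linearization limit but means the
  machinery does not extend unchanged to finite mutant densities.
* Only host evolution is implemented — parasite traits, coevolution and
  post-branching dimorphic dynamics are not.
* The closed-form calibration of $\tau_1$ applies to the baseline
  (direct-transmission, unforced) model; for the free-living model the
  shipped trade-off values are used as given.
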