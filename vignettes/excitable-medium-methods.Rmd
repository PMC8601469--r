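---
title: "Modeling mixed-population cAMP signaling as a stochastic excitable medium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mixed-population cAMP signaling as a stochastic excitable medium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dictywave)
```

## The model

During the aggregation phase of *Dictyostelium discoideum*, starving amoebae
communicate by relaying pulses of extracellular cyclic AMP. `dictywave`
simulates this as a two-variable excitable medium on an `N x N` square
lattice. Each site carries an activator `u` (the local extracellular cAMP
level; it diffuses across the whole grid, empty sites included) and each
*occupied* site carries a recovery variable `v` (the state of the cell's
cAMP receptors) and a colored-noise term `eta`:

$$\partial_t u = f(u, v) + D_u \nabla^2 u, \qquad
  \partial_t v = u - v + \eta(t), \qquad
  \partial_t \eta = -\lambda \eta + \sqrt{2 D \lambda}\, \zeta(t),$$

with $\zeta$ unit white noise. The population is mixed:

* **Proactive (cooperative) cells** amplify the signal through the cubic
  Barkley kinetics $f(u,v) = \epsilon^{-1} u (1-u)(u - u_{th})$ with
  threshold $u_{th} = (v + b)/a$. The roots at $u = 0$ and $u = 1$ are the
  rest state and the excited plateau; $u_{th}$ is the unstable firing
  threshold, raised by the recovery variable.
* **Reactive (less-cooperative) cells** do not amplify: their activator
  follows the bare linear response $u - u_{th}$. The missing
  $\epsilon^{-1}$ factor makes them an order of magnitude slower than their
  proactive neighbors.
* **Empty sites** only transport: `u` diffuses through them (an optional
  linear degradation rate, `decay`, is exposed and defaults to 0).

A lattice is described by the total occupancy `phi1` (fraction of the
$N^2$ sites carrying a cell) and the reactive fraction `phi2` (fraction *of
the occupied sites* that are reactive). Both counts are drawn exactly —
`round(phi1 * N^2)` cells, `round(phi2 * n_occupied)` of them reactive,
sampled uniformly without replacement — so the composition is deterministic
given `(N, phi1, phi2)` and reproducible given the seed. Cells do not move.

Runs start with a randomly chosen fraction `f_fire` (default 0.01) of the
occupied cells excited at `u_fire` (default 1, the excited branch). These
two knobs are deliberately explicit configuration rather than hidden
constants; the steady state does not depend on them, only the initial
growth transient does.

## Numerical scheme

The integrator (compiled code under `src/`) advances all fields with an
explicit time step `dt` except for the stiff cubic term:

* **Diffusion** is the standard 5-point stencil. Under the default
  `"noflux"` boundary an out-of-grid neighbor mirrors the edge value;
  `"periodic"` wraps. Stability requires $D_u\,dt/h^2 \le 1/4$, enforced at
  parameter construction.
* **Proactive reaction** uses the classic fast–slow treatment: the factor
  $(u - u_{th})/\epsilon$ is frozen over the step and the remaining
  logistic part is updated implicitly, which is unconditionally stable for
  the $\epsilon^{-1}$ jumps and keeps the reaction inside $[0, 1]$.
* **Boundary layer.** A site with $u < \delta$ ($\delta = 10^{-4}$) *and*
  $u \le u_{th}$ is treated as at rest: its reaction is skipped and only
  diffusion acts, while `v` keeps relaxing. The second condition matters:
  when a noise excursion drags the threshold below the current (possibly
  tiny) `u`, the cell is genuinely excited and does react. This is the
  pacemaker pathway by which colored noise nucleates waves; without it the
  fully quiescent lattice would be an absorbing state that no noise could
  ever leave. The gate applies to both cell types — sub-threshold,
  sub-$\delta$ activator levels decay to the rest point for either kinetics.
* **Reactive reaction** is explicit Euler, floored at $u = 0$: `u` is a
  concentration and a cell cannot respond its local cAMP level below zero.
  Without the floor the linear reactive subsystem (a marginally stable
  center) is pumped by the noise over long runs into unbounded collective
  oscillations with strongly negative `u`, which contradicts both the
  non-negative concentration fields and the bounded means the system is
  known to produce. With the floor and the diffusion bound above, the whole
  `u` field stays non-negative.
* **Noise** uses the exact Ornstein–Uhlenbeck discretization
  $\eta' = \eta e^{-\lambda dt} + \sqrt{D(1 - e^{-2\lambda dt})}\, z$, so
  its stationary mean (0), variance ($D$) and autocorrelation
  ($e^{-\lambda\tau}$) are step-size exact. Draws are independent per
  occupied site (a shared-draw mode exists for sensitivity analysis); noise
  enters only the `v` equation, never `u` and never empty sites.
* **Guards.** Any non-finite value aborts with the iteration and site; an
  optional ceiling `u_cap` aborts on runaway growth rather than silently
  clipping.

One integration step is one "iteration" throughout: recorded series,
crossover times and kymograph axes all count steps.

## Parameters, defaults, and the calibration

The exact kinetic constants behind the phenomenology this package
reproduces are not published, so the defaults are a one-time calibration to
the *circular-wave regime*, chosen once against three qualitative anchors
and then frozen:

1. a noise-free excitation seeded in a pure population must propagate as a
   target wave for `phi1 >= 0.4` and die out at `phi1 = 0.3` (the density
   threshold for global patterns);
2. with noise on, a pure half-occupied lattice must show repeated,
   noise-nucleated circular waves — not silence, not permanent bulk
   turbulence;
3. the nearest-neighbor synchrony index of that regime must sit near 0.94
   with a shallow decline as reactive cells are mixed in.

| parameter | default | meaning and rationale |
|---|---|---|
| `a`, `b` | 0.8, 0.07 | threshold controls; rest threshold `b/a` = 0.0875 puts the noise-free propagation cutoff between `phi1` 0.3 and 0.4 |
| `epsilon` | 0.02 | activator/recovery time-scale ratio (fast jumps ~50x the recovery rate) |
| `delta` | 1e-4 | boundary-layer size below which a sub-threshold cell is at rest |
| `D` | 0.03 | OU intensity; sets the pacemaker nucleation rate and the high-`phi2` "mist" amplitude |
| `lam` | 2 | OU rate; correlation time 0.5 time units (50 steps) |
| `dt` | 0.01 | step; 100 steps per recovery time unit |
| `h`, `D_u` | 1, 4 | lattice spacing and activator diffusivity; `D_u dt/h^2` = 0.04, and the resulting diffusion length makes the wave texture smooth at the site scale |
| `bc` | `"noflux"` | standard choice for bounded dishes; `"periodic"` available |

Two calibration choices deserve emphasis. First, the noise correlation
time: the two natural readings of a cutoff frequency "of order
$\epsilon$" — $\lambda = \epsilon$ and $\lambda = 1/\epsilon$ — are both
pre-wired in `noise_preset()`, and both fail here. Quasi-static noise
($\lambda = 0.02$, correlation 50 time units) never mean-reverts within a
run, so reactive cells with a lucky negative excursion grow without bound;
near-white noise ($\lambda = 50$) averages out before it can hold the
threshold down long enough to nucleate anything. The default $\lambda = 2$
lies between: dips last about half a recovery time, long enough to fire a
pacemaker, short enough that the mean reversion bounds reactive growth.
Second, `D_u = 4`: with `D_u = 1` the diffusion length per excitation
cycle is below one lattice spacing, the occupied/empty texture dominates
the neighbor covariance, and no parameter choice brings the synchrony
index near its target band.

## Statistics

All spatial statistics run over **all $N^2$ sites**, empty ones included,
with the plain $N^{-2}$ normalization: the mean field $\bar u(t)$, the
population standard deviation $\sigma(t)$, and the von Neumann neighbor
covariance $Cov(t)$ (quarter-weighted centered products with the four
orthogonal neighbors; edge neighbors follow the simulator's boundary
convention, which perturbs $Cov$ at $O(1/N)$ and is therefore kept
consistent). The synchrony index is the time average
$S = \langle Cov(t)/\sigma^2(t)\rangle_t$; per the Cauchy–Schwarz
inequality each summand is at most 1, with 1 meaning perfect spatial
coherence and a checkerboard reaching $-1$.

The averaging window for $S$ is not fixed by the quantity itself, so it is
configurable; the default excludes the first `n_head = 300` iterations (the
exponential-growth transient, the same window the growth line is fitted on)
and skips iterations whose variance is below `sigma_floor` ($10^{-12}$),
which would otherwise contribute 0/0 noise from a dead medium. A fully dead
window raises an explicit "undefined synchrony" error rather than returning
a silent 0.

$\log\sigma(t)$ (natural log; the base rescales slope and intercept
jointly, so the crossover is base-invariant) is summarized by an OLS line
over the first 300 iterations, a plateau equal to the mean over the last
3000 iterations, and their intersection, the crossover time $T$ between
the growth and oscillatory regimes. Kymographs show
$\sqrt{\max(u, 0)}$ along one recorded lattice row (middle row by
default) over the trailing 2000 iterations.

## Pattern labels are a heuristic

The circular/spiral/none distinction is, in the source phenomenology, a
visual one. The `classify_pattern()` layer operationalizes it with a
transparent topological heuristic: the phase
$\theta = \mathrm{atan2}(v - v_{ref}, u - u_{ref})$ around a reference
point inside the excursion loop, winding numbers on every 2x2 plaquette,
box-smoothing (radius 2) beforehand, and an amplitude mask (0.05) so that
low-amplitude regions — where the phase is numerically meaningless — cannot
contribute spurious tips. A run is `NONE` without late-time activity,
`SPIRAL` when tips persist in at least half the snapshots, `CIRCULAR` when
they appear in fewer than 10%, `NOISY` otherwise; every threshold is an
argument. The labels are advisory. At the calibrated noise level most
wave-active runs carry at least transient phase singularities from
colliding fronts, so the tip-persistence rule reads them as `SPIRAL` even
where a human would say "mostly circular"; distinguishing transient from
anchored tips would need tip *tracking*, which is out of scope. The
classifier is at its most informative at the extremes (dead or misty media
versus coherent rotating cores built synthetically), and that is exactly
how the test suite exercises it.

## What the generator emulates — and what it does not

The synthetic lattices emulate: uniformly random, immobile, mixed
populations at exact composition; random initial firing; independent
per-cell receptor noise. They deliberately do not emulate chemotaxis or
any cell movement, aggregation streaming, spatially clustered occupancy,
cell death or division, or three-dimensional geometry. Passing tests
therefore say nothing about the aggregation stage itself — only about the
signaling-relay stage on a static population.

## Scales used by the reproduction protocol

The shipped checks run the half-occupancy synchrony table at its original
400 x 400 size (3 seeds per composition) in the acceptance script and at
200 x 200 inside the test suite; the composition survey
(`phi1` 0.4–0.8 x `phi2` 0–0.5) runs at 200 x 200 with one seed per cell;
all use 6000 iterations. These sizes were chosen because the synchrony
index is insensitive to them (the 400 and 200 results agree to the third
decimal for the pure half-occupancy run) while keeping a full survey in
the minutes range on one core.

## Known limitations

* **Mean-field level.** The calibrated regime reproduces the synchrony
  column and its ordering well, but wave-active media run hotter than the
  reported mean-field band: the time-averaged $\bar u$ is about 0.16 for
  the pure half-occupied lattice, declining to about 0.03 at
  `phi2 = 0.5`, where the reported band is a flat 0.05–0.08. Thinner waves
  (smaller `D_u`) fix the level but destroy the synchrony target; the
  published parameter set presumably resolves this tension in a way the
  main-text information does not pin down.
* **Crossover ordering.** Adding reactive cells lowers the growth slope of
  $\log\sigma$ in this implementation, which *delays* the fitted crossover
  slightly, whereas the source observations report an earlier crossover in
  mixed populations.
* **First-order fronts.** The semi-implicit frozen-factor update is O(dt)
  on front speeds, so trajectory comparisons across step sizes drift
  linearly with horizon; the consistency check in the test suite uses a
  short (1 time unit) window on a developed pulse for this reason.
* The classifier caveats above.

## A minimal session

```{r example, eval = FALSE}
lat <- generate_lattice(200, phi1 = 0.5, phi2 = 0.1, seed = 1)
tr <- simulate_population(lat, model_params(), n_iter = 6000, seed = 1)
glance(tr) # S, growth slope, plateau, crossover, oscillatory-mean ubar
autoplot(tr) # mean field and log sigma with the two regime lines
autoplot(kymograph(tr)) # space-time sqrt(u) along the middle row
classify_pattern(tr)$label

cfg <- survey_config(
  phi1 = seq(0.4, 0.8, 0.1), phi2 = seq(0, 0.5, 0.1),
  N = 200, n_iter = 6000, classify = FALSE
)
surv <- run_survey(cfg)
plot_survey(surv, "S")
```
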