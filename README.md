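# dictywave

Stochastic excitable-medium simulation of concerted cAMP signaling in
mixed populations of *Dictyostelium discoideum*.

## The problem

When starving, *Dictyostelium* amoebae aggregate by relaying pulses of
extracellular cyclic AMP (cAMP): a cell whose local cAMP level `u` exceeds
a threshold fires, secretes more cAMP, then becomes refractory while its
receptor state `v` recovers. On a dish this produces the classic
target (circular) and spiral waves of excitable media. `dictywave` asks
what happens when the population is *mixed*: a fraction of cells are
"reactive/less-cooperative" — they sense and respond to cAMP but do not
amplify it — while the rest are "proactive/cooperative" amplifiers.

The model is a noisy two-variable reaction–diffusion system on an
`N x N` lattice with a fraction `phi1` of sites occupied and a fraction
`phi2` of those occupied sites reactive:

    du/dt   = f(u, v) + D_u lap(u)         (u on all sites)
    dv/dt   = u - v + eta(t)               (v on occupied sites)
    deta/dt = -lam * eta + sqrt(2 D lam) zeta(t)

with proactive kinetics `f = (1/eps) u (1-u) (u - u_th)`,
reactive kinetics `f = u - u_th`, threshold `u_th = (v + b)/a`, and
`eta` an Ornstein–Uhlenbeck (mean-reverting) noise of intensity `D` and
correlation time `1/lam` acting on the receptor variable. Integration uses
the Barkley fast–slow semi-implicit scheme with boundary layer
`delta = 1e-4`.

The package is for computational/systems biologists and excitable-media
modelers who want a fast, reproducible lattice simulator of this mixed
population plus the complete statistical readout:

* mean field `ubar(t)`, fluctuation width `sigma(t)` and its
  exponential-growth/plateau crossover time,
* the synchrony index `S = < Cov(t)/sigma^2(t) >_t` built on the von
  Neumann nearest-neighbor covariance,
* kymographs of `sqrt(u)` along a lattice row,
* a phase-singularity (spiral-tip) counting heuristic for advisory
  circular/spiral/noisy/none labels,
* a survey driver over the `(phi1, phi2)` composition plane.

## A worked example

```r
library(dictywave)

lat <- generate_lattice(200, phi1 = 0.5, phi2 = 0.1, seed = 1)
lat
#> <camp_lattice> 200 x 200, phi1 = 0.5, phi2 = 0.1 (seed 1)
#>   20000 occupied sites (18000 proactive, 2000 reactive)

tr <- simulate_population(lat, model_params(), n_iter = 6000, seed = 1)
glance(tr)
#> # A tibble: 1 x 11
#>       N  phi1  phi2  seed     S   slope intercept plateau crossover ubar_osc
#>   <int> <dbl> <dbl> <int> <dbl>   <dbl>     <dbl>   <dbl>     <dbl>    <dbl>
#> 1   200   0.5   0.1     1 0.939 0.00521     -3.75   -1.38      454.    0.144
#> # i 1 more variable: n_iter <int>
```

Half the lattice carries cells, 10% of them reactive. After the initial
exponential growth of the fluctuation width (fitted slope 0.00521 per
iteration over the first 300 iterations), the medium crosses into its
oscillatory wave regime at iteration ~454 and settles at a
`log(sigma)` plateau of -1.38. The synchrony index `S = 0.939` says the
cAMP field is spatially coherent at the neighbor scale — circular/spiral
waves, not incoherent speckle — and the post-crossover mean cAMP level is
0.144. Re-running with `phi2 = 0` gives `S = 0.943`: the reactive
minority produces the characteristic small, monotone decline of `S`
with `phi2`.

Plots and labels:

```r
autoplot(tr)                   # ubar(t) and log sigma(t) with both regime lines
autoplot(kymograph(tr))        # space-time sqrt(u), last 2000 iterations
classify_pattern(tr)$label     # advisory label, here "SPIRAL"
```

Composition survey (one row per `(phi1, phi2, replicate)`):

```r
cfg <- survey_config(phi1 = seq(0.4, 0.8, 0.1), phi2 = seq(0, 0.5, 0.1),
                     N = 200, n_iter = 6000, classify = FALSE)
surv <- run_survey(cfg)
plot_survey(surv, "S")
```

A thin CLI over the same functions lives in `inst/cli/dictywave.R`
(subcommands `simulate`, `analyze`, `classify`, `survey`, `fixtures`;
YAML/JSON configs via `write_config()`).

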