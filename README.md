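# ecoculture

Stochastic ecocultural consumer–resource dynamics under climate forcing.

`ecoculture` is an R package for simulating and analyzing a minimal
three-variable model of coupled human population growth, cumulative
culture and resource depletion:

```
drho/dt = alpha * rho * (1 - rho / (K * (1 + c)))      # logistic growth to the
                                                       # cultural carrying capacity
dc/dt   = -lambda * c + sigma * xi_t * rho             # culture: loss + density-
                                                       # amplified random innovation
dK/dt   = -eta * (K - K0(t)) - mu * rho                # resources: replenishment
                                                       # minus grazing
```

Culture `c` boosts the effective carrying capacity `K(1+c)`; innovations
`xi_t` are heavy-tailed Weibull draws (scale 1, shape 0.1), so rare
"cultural bursts" trigger population booms that deplete the resource base
`K` and collapse — stochastic boom-and-bust cycles. The baseline capacity
`K0(t)` can be forced sinusoidally to mimic slow climate cycles, and the
package quantifies 1:1 phase synchronization between the forcing and the
simulated density/culture via the analytic-signal (Hilbert-transform)
phase, wrapped phase-difference histograms, a relative-standard-deviation
metric and a Kolmogorov–Smirnov uniformity test.

Intended for researchers in paleodemography, cultural evolution and
theoretical ecology who want a reproducible, tested implementation of this
class of model: simulation, closed-form oracles, ensembles, `(lambda, mu)`
parameter sweeps and the phase-synchronization pipeline, with CSV/JSON/YAML
I/O and a thin command-line front end.

## Worked example

```r
library(ecoculture)

## the "standard run": alpha = lambda = 0.01, mu = 0.001, eta = 0.1,
## sigma = 1e-8, constant baseline capacity K0 = 1
p <- eco_params(n_steps = 20000L, seed = 1L)
traj <- simulate_ecoculture(p)
traj
#> Ecocultural trajectory: 20000 steps, dt = 1, seed = 1
#>   forcing: constant | clipping events: 0 | barren steps: 0
#>   rho in [0.01, 18.1], c in [0.017, 172.5], K in [0.8196, 1]

## how far above the culture-free equilibrium did the boom carry?
max(traj$rho) / equilibrium_fixed_point(eco_params(sigma = 0))[["rho_star"]]
#> [1] 18.2835
```

A culture burst (here to `c ~ 172`) lifted the population to 18 times the
density the environment sustains without culture
(`rho* = K0 / (1 + mu/eta) = 0.9901`); the boost varies strongly across
seeds (median ~26-fold over 20 seeds, occasionally > 50-fold). Resources
per capita (`traj$per_capita`) drop during the boom and drive the bust.

Phase synchronization with a periodic "climate" (period 10000, amplitude
0.5):

```r
pf <- eco_params(kappa = 0.5, omega = 2 * pi / 10000,
                 n_steps = 200000L, seed = 1L)
synchronization_report(simulate_ecoculture(pf))
#> Phase-synchronization report (response vs climate forcing)
#> Phase sync [rho]: rel std 59.8% (36 bins), KS D = 0.1458, p = 0
#> Phase sync [c]: rel std 19.5% (36 bins), KS D = 0.04568, p = 0
```

Both variables lock to the forcing (uniform phase differences are firmly
rejected); the locking is much tighter for density than for culture, whose
multiplicative noise blurs the phase.

Ensembles and sweeps follow the same pattern
(`run_ensemble(p, n_members = 16, seed_base = 1)`,
`eco_sweep(p, lam_values = 10^(-4:-1), mu_values = 10^(-4:-1))`), and
`vignettes/ecoculture-methods.Rmd` documents the model, the defaults and
the numerical choices.

## Command line

```sh
Rscript inst/cli/ecoculture.R simulate --n-steps 20000 --out runs/std
Rscript inst/cli/ecoculture.R sync --kappa 0.5 --omega 0.000628 --out runs/sync
Rscript inst/cli/ecoculture.R validate          # Euler vs closed-form oracles
```

Subcommands: `simulate`, `ensemble`, `sweep`, `sync`, `validate`; options
come from a YAML `--config` file with CLI flags taking precedence. Every
output directory receives the data as CSV/JSON, a `metadata.json` with the
full configuration and seed, and a checksum `manifest.json`.

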