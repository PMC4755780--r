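# swarmevol

Agent-based simulation of how **collective sensing** evolves in mobile
animal groups — the kind of distributed resource tracking seen in schooling
fish, where no individual can sense a resource gradient yet the group
climbs it.

The model couples three ingredients on a periodic two-dimensional domain:

1. **Social force** (Eq. below, left): each agent responds to its *k*
   nearest neighbours within its interaction range *l*<sub>max</sub>
   through the negative gradient of a double-exponential pair potential —
   short-range repulsion, mid-range attraction, no explicit alignment:

   U(d) = C<sub>r</sub> e<sup>−d/l<sub>r</sub></sup> − C<sub>a</sub> e<sup>−d/l<sub>a</sub></sup>

2. **Autonomous force**: agents modulate only their *speed* in response to
   the local resource value S(x) (a klinokinesis — no gradient steering):

   F<sub>a</sub> = [Ψ − η|v|²] v/|v|,  Ψ = ψ<sub>0</sub> − ψ<sub>1</sub> S(x)

   For Ψ > 0 the preferred speed is √(Ψ/η); for Ψ ≤ 0 the agent stops
   (station-keeping). The sign and size of Ψ set the collective state:
   *station-keeping* (Ψ < 0), *cohesive* (small Ψ > 0), *dispersed*
   (large Ψ), with abrupt, hysteretic transitions between them.

3. **Evolution**: the resource is a set of drifting, diffusing, relocating
   Gaussian peaks; fitness is the mean resource an individual experiences
   over its lifetime; offspring are drawn in proportion to relative
   fitness and inherit (ψ<sub>0</sub>, ψ<sub>1</sub>, l<sub>max</sub>)
   with small Gaussian mutations. An asocial control pins l<sub>max</sub>
   between the repulsion and attraction scales (repel, never attract).

The package provides the particle dynamics (Rcpp core), the resource
environment (including a depletion variant), the generational loop with
invasion experiments, and the collective-state analyses: hysteresis and phase
sweeps of ⟨d10NN⟩ (mean distance to the ten nearest neighbours), potential
energy, Kullback–Leibler divergence between agent density and the resource
distribution, arrival curves with linear/exponential model comparison, and
group–peak size matching. A methods vignette
(`vignettes/collective-sensing-model.Rmd`) documents the model, the
discretization and every open design choice.

## Worked example: collective tracking of a resource peak

A population with evolved-state trait means (ψ0 = 3, ψ1 = 2.45,
lmax = 29) is dropped uniformly at random around a single slowly
drifting, diffusing peak and tracked for 1200 steps:

```r
library(swarmevol)

social_params()
#> <social_params> Cr=1.1 Ca=1 lr=1 la=7.5 k=25 m=1 eta=1 gamma=0.01 tau=1 (C=1.1, l=0.133)

pair_balance_distance(social_params())   # pair force changes sign here
#> [1] 2.434861

tk <- track_run(trait_set(3, 2.45, 29), n_agents = 150, n_steps = 1200,
                seed = 42)
tk$counts[c(100, 400, 800, 1200), ]
#>         t count
#> 100   100     1
#> 400   400     8
#> 800   800    12
#> 1200 1200    21

head(tk$kl, 3); tail(tk$kl, 3)
#>     t       kl
#> 1 100 14.48270
#> 2 200 12.79837
#> 3 300 10.85680
#>       t       kl
#> 10 1000 4.793941
#> 11 1100 4.265033
#> 12 1200 3.105763
```

Agents accumulate within one decay length of the wandering peak centre
(from the uniform-baseline one agent to 21 of 150), and the KL divergence
between the resource distribution and the agent density falls from ≈ 14.5
to ≈ 3.1 as the population comes to mirror the resource — even though no
individual senses a gradient. The same run with `lmax = 2` (the asocial
control: repulsion only) accumulates about half as many agents and ends
more than twice as far from the resource distribution (KL ≈ 7.5).
`tk$arrival` additionally fits the two arrival laws — linear
κ<sub>a</sub>t + c versus self-reinforcing exponential
κ<sub>s,1</sub> + e<sup>κ<sub>s,2</sub>t</sup> — and compares them by AIC;
on single runs the preference is noisy, so model comparison is best done on
replicate-mean curves over the accumulation window (see the methods
vignette).

Other entry points: `hysteresis_sweep()` / `transition_points()` for the
collective-state transitions, `run_evolution()` / `invasion_experiment()`
for the evolutionary dynamics, `phase_sweep()`, `group_peak_matching()`,
and `make_scenario()` for the deterministic test scenarios. A thin command
line sits at `inst/cli/swarmevol` (subcommands `evolve`, `simulate`,
`hysteresis`, `track`, `match-peaks`, `invade`, `fixtures`).

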