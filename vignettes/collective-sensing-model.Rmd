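---
title: "An agent-based model of the evolution of collective sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of the evolution of collective sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmevol)
```

## The model

`swarmevol` simulates populations of self-propelled foragers on a periodic
two-dimensional domain (a square torus, edge length 346 in units of the
repulsion length scale `lr`). Each agent carries three heritable behavioural
traits and obeys two forces.

**Social force.** Agent *i* responds to the set *N_i* of its `k` nearest
neighbours lying within its interaction range `lmax`. The force is the
negative gradient of a double-exponential pair potential,

$$U(d) = C_r e^{-d/l_r} - C_a e^{-d/l_a},$$

so each neighbour at minimum-image distance *d* contributes
$[(C_r/l_r)e^{-d/l_r} - (C_a/l_a)e^{-d/l_a}]\,\hat r$ along the unit vector
from the neighbour to the focal agent. With the default parameters
($C_r = 1.1$, $C_a = 1$, $l_r = 1$, $l_a = 7.5$) the pair force is repulsive
below $d^{*} = \ln(8.25)/(1 - 1/7.5) \approx 2.43$ and attractive beyond it,
decaying exponentially. There is no explicit alignment term: collective
motion is emergent. Two agents are socially connected when at least one
holds the other in its neighbour set; a *group* is a connected component of
that graph.

**Autonomous force.** Agents do not steer up resource gradients. They only
modulate speed: $F_a = [\Psi_i - \eta |v|^2]\, v/|v|$ with
$\Psi_i = \psi_0 - \psi_1 S(x_i)$, where $S$ is the local resource value.
For $\Psi > 0$ the stable speed is $\sqrt{\Psi/\eta}$; for $\Psi \le 0$ the
agent decelerates to rest (station-keeping). This speed-only response is a
klinokinesis: slowing in favourable locations concentrates individuals there
without any gradient sensing.

**Resource environment.** The resource is a sum of `M` Gaussian peaks,
$S(x) = \sum_p \lambda_0 e^{-|x - x_p|^2/\lambda_1^2}$ (defaults
$\lambda_0 = 10$, $\lambda_1 = 20$). Peaks drift, diffuse (per-component
standard deviation `beta` per step), and relocate uniformly at rate
$1/\tau_p$ (default $\tau_p = 1500$), their amplitude resetting to the
configured value on relocation — under the optional depletion variant
(consumption $u\,S(x_i)$ per agent-step, attributed to peaks in proportion
to their contribution) this is the regeneration mechanism that keeps the
long-run mean resource stationary.

**Evolution.** Each generation, `N` agents live `T_gen` steps; fitness is
the mean resource experienced. Parents are drawn in proportion to relative
fitness; offspring inherit $(\psi_0, \psi_1, l_{max})$ perturbed by
independent Gaussian mutations (defaults $\sigma_{\psi} = 0.05$,
$\sigma_{l_{max}} = 0.5$), with $l_{max}$ clipped to $[0, 30]$. The asocial
control pins $l_{max} = 2$ (between $l_r$ and $l_a$: repulsion without
attraction).

## Discretization

Within a time step $\tau$ (default 1) the social force and the resource
value are evaluated once and frozen, as the model prescribes: agents act on
information acquired at the start of the step. The within-step integration
uses `n_sub` (default 10) semi-implicit Euler sub-steps with an operator
split: the frozen social kick updates the velocity, then the autonomous
force is applied as a scalar speed update along the current heading, then
the position advances. Two numerical guards matter:

* the autonomous speed update is floored at zero within a sub-step. The
  force acts along $v/|v|$, so physically it can decelerate an agent at most
  to rest; an unsplit explicit update instead reverses the heading when
  $h\,|\Psi| > |v|$ and stalls the speed near $h\,|\Psi|$ instead of zero,
  which corrupts the station-keeping state this model's phenomenology
  depends on;
* at speeds below $10^{-8}$ the heading is undefined and the autonomous
  force is zero; coincident pairs (distance below $10^{-12}$) contribute no
  social force.

After the sub-steps, a noise vector of *exact* magnitude `gamma` (default
0.01) with uniform heading is added to each velocity, and positions wrap
onto the torus. All agents update synchronously from the pre-step state;
with `gamma = 0` trajectories are bit-reproducible for a given seed. The
neighbour search is brute force over minimum-image distances (ties broken
by agent index); populations here are a few hundred agents, and brute force
is also the contract any future spatial index must reproduce exactly.

## Collective states and their analysis

With a uniform resource ($S = 0$) and a shared $\Psi$, the population
occupies one of three states: *station-keeping* ($\Psi < 0$; frozen
positions), *cohesive* (small positive $\Psi$; dense groups, mean distance
to the ten nearest neighbours $\langle d_{10NN}\rangle \approx 1.5$), and
*dispersed* (large $\Psi$; near-ideal-gas spacing). `classify_state()`
labels agents by the thresholds 0 and 2.95. The transitions are abrupt and
hysteretic, like a first-order phase transition: `hysteresis_sweep()`
implements the two-branch protocol (equilibrate, measure
$\langle d_{10NN}\rangle$, step $\Psi$; state carried over between grid
points — re-equilibrating from scratch would erase the memory that
hysteresis consists of). `transition_points()` reports the midpoint of the
grid step with the largest change per branch. The dispersed-to-cohesive
collapse is nucleation-limited, so its location depends on population size,
domain size and equilibration time; the package's protocols use the
reference domain (edge 346) at the configured `N`.

`potential_energy()` provides the complementary order parameter (mean pair
potential over neighbour sets), and `phase_sweep()` maps
$\langle d_{10NN}\rangle$ over one social parameter crossed with $\psi_0$,
with `phase_boundary()` locating the steepest-gradient contour empirically.

## Resource tracking and collective computation

A population with evolved traits ($\psi_0 \approx 3$,
$\psi_1 \approx 2.45$, $l_{max} \approx 29$ — the trait means of the
evolutionarily stable state, ESSt) satisfies
$\psi_0 - \psi_1 \lambda_0 < 0$: agents cross from dispersed through
cohesive into station-keeping as they climb the resource profile. An
isolated agent approaching a peak stops where $\Psi = 0$, i.e. at radius
$r_0 = \lambda_1\sqrt{\ln(\psi_1\lambda_0/\psi_0)}$ (about 29 length units
for the ESSt traits — *outside* one decay length). Accumulation at high
resource values is therefore an intrinsically collective and dynamic
process: the peak must move relative to its surrounding shell of parked
agents, sweeping them into its core, while social attraction recruits
passers-by to the growing aggregate. `track_run()` implements this protocol
with a single peak drifting slowly (0.06 per step) and diffusing
(sd 0.5 per step) — the regime in which tracking operates; drift at the
agents' own speed scale (about $\sqrt{3}$ for dispersed ESSt agents) makes
peaks untrackable and the social advantage collapses. It reports arrival
counts within one decay length of the current peak centre and the
Kullback-Leibler divergence between the annulus-integrated resource
distribution and the radial agent density about the current centre
(`kl_divergence_to_resource()`; 30 annuli to three decay lengths, additive
regularization $10^{-9}$, direction KL(resource‖agents) so the divergence
falls as the agent density comes to resemble the resource).

`arrival_curve()` fits the two accumulation laws — linear $\kappa_a t + c$
(independent arrivals) and exponential $\kappa_{s,1} + e^{\kappa_{s,2} t}$
(self-reinforcing social recruitment) — by least squares and compares them
by AIC. Both laws describe the *initial* accumulation, so the bundled
protocols evaluate them on the window up to the first time the counts reach
80% of their run maximum, and compare models on replicate-mean curves
(single runs repeatedly lose and recapture the wandering peak).
`group_peak_matching()` time-averages, for each peak, the size of the group
whose torus circular-mean centroid lies nearest the peak centre, pairing it
with the integrated peak mass $\lambda_0 \pi \lambda_1^2$; the bundled
size-matching protocol uses stationary, well-separated peaks, which
isolates the group-size allocation from the tracking dynamics.

## Choices made where the design was open

* **Peak motion for dynamic-environment studies.** The reference parameter
  tables give two peak-velocity settings: a drift of 1 per step in the
  headline table and 0.06 with diffusion 0.5 in the demonstration runs. The
  two are not interchangeable: a peak moving as fast as the agents
  themselves cannot be tracked by speed modulation plus attraction (we
  verified that a group seeded on such a peak loses it within a hundred
  steps, and that evolved social populations then do no better than the
  asocial control). The tracking, arrival and group-matching protocols
  therefore default to the slow-drift setting; the fast-drift values remain
  available through the configuration block. The configuration defaults
  themselves keep the headline-table values.
* **Generation length.** `T_gen` defaults to 1500 steps so a lifetime sees
  about one relocation per peak; the scaled evolutionary protocols in the
  acceptance suite use `T_gen = 500` with 300 generations at `N = 200`.
* **Initial traits.** Uniform draws $\psi_0, \psi_1 \sim U(0, 1)$,
  $l_{max} \sim U(0, 30)$: naive, weakly-responsive, unbiased between
  social and asocial. $\psi_0$ and $\psi_1$ are clipped below at zero under
  mutation (negative baseline speed or sensitivity has no reading in the
  model); no upper bound is imposed.
* **Fitness under depletion** uses the pre-depletion resource value each
  step, keeping "mean resource experienced" well-defined while the
  consumption accounting stays in the environment module.
* **Per-generation state.** Positions and velocities re-randomize each
  generation (uniform positions; speeds uniform on $[0, 0.1]$ with uniform
  headings); the environment persists across generations by default.
* **Hysteresis error bars** aggregate over replicate populations (two
  standard errors), not over agents.
* **Randomness.** Everything runs off R's RNG; `derive_seed()` expands one
  global seed into independent per-module streams by a fixed integer hash,
  so adding an analysis stage never perturbs the dynamics' draws.

## What the synthetic scenarios do and do not show

The fixture catalogue (`scenario_catalog()`) pins the mechanically critical
configurations: an isolated pair at the force-balance separation, ESSt-like
tracking of a slowly-moving peak, the repulsion-only asocial control, and
the two perturbed baseline-speed populations that fail to track (means 0.4
and 8.8). Synthetic arrival series (`synth_counts()`) support exact
fit-recovery checks. These scenarios exercise the model's machinery, not
real animal data: passing them shows the implementation realizes this
model faithfully, not that the model describes any particular fish school.
Real trajectory data have body-size effects, walls, anisotropic vision and
temporally correlated noise, all outside this model family.

## Problem sizes and limitations

The bundled protocols run at desk scale: hysteresis at `N = 200` with
2000-step equilibration and 10 replicates; evolution at `N = 200`, 300
generations of 500 steps; tracking at `N = 200` over a few thousand steps
with about 20 seeds. The reference-scale experiments (N = 500, thousands of
generations, 50-1000 replicates) change quantitative details —
nucleation-limited transition locations shift with population and domain
size, and evolved trait values tighten with longer runs — but not the
qualitative structure. Known limitations: fitness at desk scale is
luck-dominated early in evolution, so trait trajectories are noisy; the
dispersed-to-cohesive collapse location is a kinetic (not thermodynamic)
quantity; and the exponential-versus-linear arrival discrimination needs
many replicates because single runs repeatedly lose and recapture the
peak. The continuum/linear-stability analysis of the transition boundary
and the closed-form arrival-rate derivations are out of scope; only their
empirical counterparts are provided.
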