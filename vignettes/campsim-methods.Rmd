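---
title: "campsim: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{campsim: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(campsim)
```

campsim simulates hunter–gatherer camps as interacting agents on a
time-dependent habitat-suitability landscape. This vignette is the
package's own account of the model, the tunable parameters, the numerical
choices, and the design decisions taken where the formulation was open.

## The model

### State

An agent is a camp with position $X_\alpha(t)$ in planar km coordinates,
population $D_\alpha(t)$ (a positive real; people), and cultural status
$S_\alpha(t) \in \mathbb{Z}_{\ge 0}^c$. The system state is the collection
of all live agents. Time advances in months; the landscape is indexed in
years BP, decreasing as simulation time advances
($\mathrm{bp} = \mathrm{bp}_0 - t/12$).

### Mobility

Camps relocate by the SDE

$$dX_\alpha = -\nabla\big(V(X_\alpha, t) + U_\alpha(X)\big)\,dt
  + \sigma(X_\alpha)\,dB_\alpha,$$

integrated with the Euler–Maruyama scheme at step $\Delta t$ = 1 month.

* **Environmental potential.** $V(x,t) = -w_\mathrm{env}\, s(x,t)$ with
  $s \in [0,1]$ the suitability. The suitability→potential transform is
  not pinned down by the formulation we implement; a negative linear map is
  the simplest monotone choice that makes attractive areas minima of $V$,
  and $w_\mathrm{env}$ (dimensionless, default 1) is exposed for
  calibration. The gradient is taken by central differences (step =
  half a cell) on the bilinear interpolant of the active slice, which keeps
  $V$ pluggable — `potential_stub()` injects analytic potentials for
  integrator benchmarks.
* **Pair interactions.** $U_\alpha = \sum_{\beta \ne \alpha}
  W(\lVert X_\alpha - X_\beta \rVert)$ with the Morse-like
  $W(d) = a_\mathrm{rep} e^{-d/l_\mathrm{rep}} - a_\mathrm{att}
  e^{-d/l_\mathrm{att}}$, truncated at the long-range radius (50 km).
  The default strengths put the zero crossing of the pair force at
  $d_\mathrm{rep} = 10$ km: a repulsive core keeps foraging areas from
  piling onto one point, a weak attractive tail works against isolation.
  Coincident camps (fresh fission twins) are separated along a
  deterministic direction hashed from the id pair, with the force magnitude
  capped at `f_max`; this keeps runs reproducible without spending RNG
  draws.
* **Noise and barriers.** $\sigma(x) = \sigma_0 (1 - \mathrm{friction}(x))$,
  floored at a small multiplier in passable terrain and exactly zero where
  friction = 1. Proposed positions landing outside the domain or in
  friction-1 cells are rejected (the camp stays put for that step) —
  the simplest rule consistent with terrain that is effectively never
  crossed. Displacements ≥ 2 km count as residential moves.

The integrator's quantitative oracle is the Ornstein–Uhlenbeck benchmark:
on $V = k\lVert x\rVert^2/2$ with $k = 1$, $\sigma_0 = 0.4$,
$\Delta t = 0.01$, the empirical per-coordinate stationary variance must
match $\sigma^2/(2k) = 0.08$ within 5% (the acceptance suite runs
$10^6$ steps).

### Demography

The local population of camp $\alpha$ is
$L_\alpha = D_\alpha + \sum_\beta D_\beta\,
\mathrm{lens}(d_{\alpha\beta}, r_f)/(\pi r_f^2)$, the neighbours weighted by
the exact circle–circle intersection of the two foraging discs
($r_f = 20$ km; zero from tangency at $2 r_f$). The carrying capacity is
linear in the disc-integrated suitability,
$K_t(x) = \kappa \sum_{\text{cells} \in r_1(x)} s \cdot A_\mathrm{cell}$.
While $L_\alpha < K_t(X_\alpha)$ the camp grows as $D\,e^{\rho_g \Delta t}$,
otherwise (ties included — the growth condition is strict) it declines at
$\rho_d$. Camps exceeding $h_\mathrm{fis} = 60$ split into two equal halves
at the same position and status (the parent keeps its id — a logging
convention, not a model assumption); camps below $h_\mathrm{fus} = 18$
merge into the *nearest* live camp within $r_2$ (processed
smallest-population-first, ties by lower id, current state re-checked, so
cascades are deterministic), or go extinct when none is in range.
Progressive merges take per-feature maxima — the absorbing camp instantly
learns every variant its partner knew. Fission and fusion conserve people
exactly; only extinction removes them.

### Culture

The interaction network is banded by distance:
$A_{\alpha\beta} = \varphi_1$ within $r_1 = 20$ km, $\varphi_2$ within
$r_2 = 50$ km (both boundaries inclusive), 0 beyond. Within each monthly
step the network and therefore the rate catalogue are frozen and a standard
Gillespie loop executes events (rates are refreshed after every event,
since they depend on the state):

* progressive: innovation at $\gamma_i$ per camp-feature; loss at
  $\lambda_i$ (zero at the floor value 0); adoption of **one** variant from
  a neighbour $\beta$ at rate $A_{\alpha\beta}\max(S_{\beta i} - S_{\alpha
  i}, 0)$, the source drawn proportionally to its summand. Linearity in the
  trait difference is the minimal monotone choice and makes each variant
  independently learnable; an indicator kernel is available
  (`adoption_kernel = "indicator"`).
* non-progressive: spontaneous switches at $\gamma_i$, uniform over the
  *other* $Q - 1$ values (a change must change state); neutral copying of a
  neighbour's exact value at rate $A_{\alpha\beta}
  \mathbf{1}[S_{\beta i} \ne S_{\alpha i}]$. $Q$ defaults to 16; the
  formulation only requires it finite.

Event logs are replayable: applying the log to the initial state
reproduces the final state exactly, which the test suite asserts.
The event-system oracles are Poisson innovation counts, the pure-death
expectation $5/\lambda$ for decay from trait 5, and the
competing-exponential consensus time $1/(2\varphi_1)$ for a two-camp
non-progressive system.

### Engine

The substep order within a month is fixed and part of the API: landscape
slice refresh → Euler–Maruyama move (+ move logging) → network rebuild →
Gillespie window → carrying-capacity population update → fission → fusion.
The order is a convention (the formulation leaves it open): the network
used for culture reflects post-move positions, and fission/fusion act on
post-growth populations. One global seed derives independent RNG streams
for initialisation, mobility and culture, so disabling culture does not
perturb the mobility draws (the ablation test relies on this). Runs are
byte-reproducible given (config, seed); checkpoints (`sim$state`) resume
bit-exactly and may be resumed under a modified landscape (the isolation
experiment does exactly that).

Initialisation follows the stated rules: positions sampled from the
equilibrium distribution of the initial slice (cell probability ∝
suitability, uniform within the cell), populations uniform on
$[h_\mathrm{fus}, h_\mathrm{fis}]$, statuses all-zero (progressive) or
uniform on $\{0..Q-1\}^c$ (non-progressive). An optional burn-in runs the
full dynamics on the frozen initial landscape before logging starts.

## Parameters

| symbol | meaning | unit | default |
|---|---|---|---|
| $r_f = r_1$ | foraging / short-range radius | km | 20 |
| $r_2$ | long-range radius | km | 50 |
| $N_0$ | starting camps | – | 300 |
| $h_\mathrm{fus}, h_\mathrm{fis}$ | fusion / fission thresholds | people | 18 / 60 |
| $\rho_g, \rho_d$ | growth / decline rates | month$^{-1}$ | 0.001 |
| $\gamma_i$ (progressive) | innovation rate | month$^{-1}$ | $10^{-4}$ |
| $\gamma_i$ (non-progressive) | switch rate | month$^{-1}$ | $10^{-3}$ |
| $\lambda_i$ | loss rate | month$^{-1}$ | 0.02 |
| $\varphi_1, \varphi_2$ | short / long-range adoption | month$^{-1}$ | 0.05 / 0.005 |
| $\sigma_0$ | noise scale | km month$^{-1/2}$ | 0.4 |
| $\Delta t$ | step | month | 1 |
| $w_\mathrm{env}$ | potential scale | – | 1 |
| $\kappa$ | capacity coefficient | people km$^{-2}$ | $60/(\pi\,20^2)$ |

$\gamma_i$ and $\lambda_i$ accept the studied ranges
($10^{-5}$–$10^{-4}$, $10^{-4}$–$10^{-3}$, 0.01–0.03); the defaults are the
high-innovation setting used in the headline analyses and the mid/low
adoption pair. $\kappa$'s default makes a fully suitable foraging disc
support ≈ 60 people — one camp at the fission threshold; it is a free
calibration constant, since the empirical suitability→density relationship
behind the original landscapes is not part of this package.

## The synthetic landscape generator

`synth_landscape()` emulates the features of palaeo-suitability projections
that matter to the dynamics: smooth patchy fields in $[0,1]$ (white noise
smoothed at a chosen correlation length, squashed through the normal CDF),
piecewise-constant in time with abrupt changes at slice boundaries,
AR(1)-correlated underlying fields between consecutive slices
(`slice_cor = 0.7`) so landscapes drift rather than reshuffle, optional
impassable barrier corridors (friction 1, suitability 0), and deterministic
output given a seed. `patch_landscape()` builds controlled Gaussian-bump
geometries for the fragmentation and isolation experiments.

What it does **not** emulate: real spatial anisotropy, coastlines and
rivers, the empirical marginal distribution of ENM suitabilities, any
correlation between suitability and friction, and real time-slice spacing
(1000–2000 years). Tests passing on synthetic landscapes therefore
validate the mechanics and the qualitative phenomena, not the quantitative
mobility triple or correlation magnitudes of full-scale runs on real
landscape stacks (which the package accepts via `read_landscape()`:
one ESRI ASCII grid per slice plus a CSV time index — the plain-text
raster format, chosen so landscapes round-trip without binary
dependencies).

## Reduced-scale study conditions

The validation experiments run at a desk scale chosen once:
100 × 100 cells of 5 km (500 × 500 km), 10 slices over the horizon,
$N_0 = 150$ camps, 2000 simulated years, 5 seeds, preceded by a 200-year
burn-in on the frozen first slice so the arbitrary initial camp count
relaxes to the landscape's own equilibrium before anything is measured.
Two calibrations differ from the package-wide defaults and are stated
here as the package's own choices:

* $w_\mathrm{env} = 250$. With $w_\mathrm{env} = 1$ the drift on a
  5-km-cell landscape is orders of magnitude below the $\sigma_0 = 0.4$
  noise and camps barely respond to the landscape; 250 makes typical
  drifts ~0.1–1 km/month so suitability actually shapes mobility. The
  original technical scaling constants are not published alongside the
  model, so this is a calibration, not a reproduction.
* $\kappa = 90/(\pi\,20^2)$ (a fully suitable disc supports ≈ 90 people,
  ~1.5 camps). At the 60-person default, mid-range suitabilities put the
  local capacity below the fission threshold almost everywhere and
  fission–fusion turnover freezes; the slightly higher coefficient keeps
  the fission–fusion cycle active at the suitabilities the synthetic
  fields actually produce.

At this scale the landscape supports an equilibrium of roughly 10–30 camps;
slice changes drive demographic expansions and crashes, which is what the
population–complexity correlation experiments measure.

## The isolation experiment

`isolation_experiment()` builds a dumbbell landscape — a large source
patch and a small peripheral patch joined by a habitable corridor ridge —
runs it connected to `t_switch`, then inserts an impassable vertical strip
and resumes from the checkpoint. The strip width is the physically
meaningful knob, because interaction is purely distance-based while
movement is friction-limited:

* width > $r_2$: all contact ends. The small patch (≈ 3 camps) is below
  the critical mass at which innovation plus internal re-adoption outrun
  loss, so its repertoire stagnates and decays relative to the source —
  the package's rendition of the loss of complex skills under complete
  isolation.
* $r_1$ < width < $r_2$: residential mobility is cut but long-range
  adoption survives. With $\lambda_i \le \varphi_2$ the cross-barrier
  inflow keeps the small patch tracking the source.

A linear adoption kernel self-compensates: lowering $\varphi_2$ mainly
widens the equilibrium complexity gap ($\approx \lambda/(\varphi_2 k)$ for
$k$ cross-barrier contacts) rather than severing the patch, which is why
the collapse arm uses full isolation plus the upper studied loss rate
(0.02) and the maintenance arm uses $\lambda = \varphi_2 = 0.01$ with
long-range contact. The reported quantity is the retention ratio
(post- over pre-isolation mean complexity of the small patch).

## Clustering choices

Mobility clusters use an in-package hierarchical density-based clusterer
(core distances → mutual reachability → single-linkage hierarchy →
condensed tree at `min_cluster_size` → excess-of-mass selection), the
method family the analysis calls for, implemented directly because no such
clusterer ships with the available R stack; its behaviour is cross-checked
in the tests against the reference semantics (two well-separated blobs →
two clusters; sparse scatter → noise; duplication invariance). The root
component is selectable via `allow_single_cluster` — `mobility_clusters()`
enables it, since one cohesive occupied region is a legitimate mobility
cluster. `min_cluster_size` defaults to about five camps' worth of pooled
samples; pooled clouds are subsampled to 2000 points, evenly strided, for
cost control.

Cultural clusters binarise the time-averaged status-closeness matrix
(exact equality for non-progressive statuses; Euclidean distance ≤
$\varepsilon = 2$ trait units for progressive ones — supplementary details
of the original closeness threshold are not available, so both
$\varepsilon$ and the binarisation threshold $\theta = 0.5$ are exposed)
and take connected components, so closeness is transitive across chains by
construction. Windows are the static-landscape intervals; trajectories are
sampled every 10 years of model time.

## Numerical details and degenerate inputs

* Bilinear interpolation treats grid values as cell centres, flat-padded
  inside the half-cell border, 0 outside the domain; friction lookups use
  the containing cell so barrier cells are exactly impassable.
* The engine's carrying capacity uses a per-slice disc-convolution grid
  interpolated at camp positions (identical to the exact disc sum at cell
  centres); `carrying_capacity()` itself evaluates the exact disc sum.
* Simpson diversity uses joint status-vector identity (the stricter
  reading of "share the same trait values across all features");
  a per-feature variant sits behind `per_feature = TRUE`. Duplicating a
  *rare* status can raise evenness and hence diversity — the tested
  invariant is that duplicating the modal status cannot.
* Local time at $L = K$ takes the decline branch (the growth condition is
  strict); populations and thresholds are compared as reals, never rounded.
* Zero agents terminate a run gracefully (`extinct = TRUE`), and an
  all-zero landscape refuses equilibrium sampling with a clear error.

## Known limitations

* No within-camp individual processes, age/sex structure, or
  culture-dependent fitness; mobility is independent of cultural status
  (matching the modelled scope).
* Planar km geometry; no geodesy, no anisotropic friction.
* The desk-scale experiments reproduce signs and orderings (positive
  population–complexity correlation rising across adoption conditions;
  more clusters on fragmented landscapes; isolation-driven decay), not the
  full-scale magnitudes, which depend on the external landscape stack.
* `hg_sweep()` exposes the parameter grids (adoption pairs, thresholds) at
  reduced scale; full 120 000-year sweeps are out of scope.
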