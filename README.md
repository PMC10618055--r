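# campsim

Spatio-temporally explicit agent-based simulation of hunter–gatherer camps:
residential mobility on a changing habitat-suitability landscape,
fission–fusion demography against a local carrying capacity, and
event-driven cultural evolution on a distance-banded interaction network.

## The model

Each agent is a camp with a position `X_a(t)` (km), a population `D_a(t)`
(people) and a cultural status `S_a(t)` (a vector of `c` integer features).

**Mobility.** Camps move by the SDE

```
dX_a = -∇( V(X_a, t) + U_a(X) ) dt + σ(X_a) dB_a
```

integrated with the Euler–Maruyama scheme at a one-month step.
`V = -w_env · s(x, t)` is the environmental potential (high suitability `s`
attracts), `U_a = Σ_b W(|X_a - X_b|)` is a Morse-like pair potential
(repulsive core so camps keep their foraging areas apart, weak attractive
tail against isolation), and `σ(x) = σ0 (1 - friction(x))` scales the noise
so impassable terrain is never crossed. Displacements of at least 2 km count
as residential moves.

**Demography.** The local population around a camp counts its own members
plus neighbours weighted by foraging-disc overlap; while it is below the
local carrying capacity `K_t(x) = κ · ∫_disc s` the camp grows exponentially
(rate 0.001/month), otherwise it declines. Camps above 60 people split in
two; camps below 18 merge into the nearest camp within 50 km (a progressive
merge takes per-feature maxima — the merged camp knows every variant either
partner knew) or go extinct if none is in range.

**Culture.** A Gillespie event system runs within each monthly step on the
network `A_ab ∈ {φ1, φ2, 0}` (≤ 20 km, ≤ 50 km, beyond). Progressive
features gain variants by innovation (`γ`), lose them (`λ`, floored at 0)
and adopt from more knowledgeable neighbours at a rate proportional to the
trait difference. Non-progressive features switch spontaneously and are
copied neutrally (Axelrod-style).

**Analysis layer.** Mobility statistics (moves/yr, km/move, km/yr), Simpson
diversity of full status vectors, mean trait complexity, density-based
mobility clusters (in-package hierarchical density clustering over pooled
trajectories), cultural clusters (connected components of a time-averaged
status-closeness matrix), cluster cell maps and overlap tables.

## A worked example

```r
library(campsim)

L <- synth_landscape(nx = 60, ny = 60, cell_size = 5, n_slices = 4,
                     smoothness = 50, bp_start = 200, bp_end = 0, seed = 42)
cfg <- hg_config(L, horizon = 2400, N0 = 60, seed = 1,
                 lparams = landscape_params(env_weight = 250,
                                            kappa = 90 / (pi * 400)),
                 metrics_stride = 120, traj_stride = 120)
sim <- hg_run(cfg)
sim
#> <hg_sim> progressive, 2400 months, 8 camps (214 people)
#>   moves: 429 (7.2 km mean); cultural events: 7535; demographic events: 58
glance(sim)
#> # A tibble: 1 × 9
#>   months n_agents total_population simpson mean_complexity moves_per_year ...
#> 1   2400        8             214.   0.219            3.62         0.0742
```

Over 200 simulated years on a 300 × 300 km synthetic landscape, the 60
starting camps relax to the carrying-capacity-limited equilibrium (8 camps,
~214 people), making 429 residential moves of 7.2 km on average; the camps
accumulate a mean trait complexity of 3.6 variants per feature and keep a
Simpson diversity of 0.22 (probability 0.78 that two random camps share the
same full status vector). `tidy(sim)` returns the sampled metrics series,
`autoplot(sim)` plots it, and `mobility_clusters()`, `cultural_clusters()`
and `cluster_overlap()` reproduce the clustering analyses.
`mobility_comparison(sim)` prints the run's mobility triple next to the
ethnographic reference rows (Aka 8 moves/yr, 7 km, 60 km/yr; Mbuti 5–11,
5–8, 57); matching those values quantitatively requires the full-scale
palaeo-landscape stack, supplied via `read_landscape()` as one ESRI ASCII
grid per time slice plus a CSV time index.

A thin command-line interface (`inst/cli/campsim.R`) exposes `simulate`,
`metrics`, `validate-mobility`, `cluster` and `make-landscape` over a YAML
configuration using the standard parameter names (`r_f`, `h_fus`, `h_fis`,
`gamma_i`, `lambda_i`, `phi_1`, `phi_2`, `r_1`, `r_2`, `sigma`, ...).

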