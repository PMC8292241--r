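---
title: "Modelling habitat networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling habitat networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habnet)
```

# The generative model

`habnet` treats an animal habitat as a spatial graph: patches (nodes) with
coordinates and optional attributes, links denoting *potential* movement
of a focal species. The model is built on three premises:

* spatial proximity is the first-order driver of potential connectivity,
  so link weights default to the reciprocal Euclidean distance
  `W(D) = 1/D`;
* proximity does not *determine* connectivity — barriers can sever close
  patches and corridors can join distant ones — so link presence is
  stochastic, with removal probability following the sigmoid
  `P(D) = [1 + exp(-λ(D - μ))]⁻¹`;
* landscape geometry matters, so the domain is a rectangle of area `A`
  and side `L` whose aspect ratio `L : A/L` ranges from square plains to
  narrow valleys.

Generation composes four stages (`generate_network()`): uniform (or
user-supplied) coordinates, the complete distance-weighted graph,
independent Bernoulli link removal, and optional rewiring of disconnected
components into a single connected network.

## Parameters

| parameter | meaning | units | default | notes |
|---|---|---|---|---|
| `A` | landscape area | length² | 25 | with `L` fixes the extent `[0,L] × [0,A/L]` |
| `L` | side length | length | 5 | `L = sqrt(A)` gives a square |
| `N` | number of patches | count | 30 | matched to a target network when fitting |
| `lambda` | sigmoid steepness | 1/length | 0.35 | `λ → 0`: distance-blind (≈ Erdős–Rényi at p ≈ 0.5); `λ → ∞`: hard threshold at `μ` |
| `mu` | critical distance | length | 5 | `P(μ) = 0.5` exactly |
| `eta` | rewiring-weight scaler | — | 1 | rewired links weigh `D^-η`; within-component weights are never touched |
| `p_stay` | staying probability per timestep | — | 0.5 | movement otherwise follows normalized link weights |
| `pi` | per-contact infection probability | per timestep | 0.05 | co-located contact model |
| `rho` | recovery probability | per timestep | 0.01 | recovered individuals are immune |

The patch attributes `U` (heterogeneity) and `V` (size) have no natural
default distribution, so `sample_layout()` leaves them unset unless the
caller supplies a sampler; they are carried through generation and file
round-trips but play no role in link formation under the default kernel.
Alternative kernels (cost-distance, dispersal kernels, attribute
similarity) plug in through the single-argument `kernel` hook of
`build_complete_graph()` / `generate_network()`; only the reciprocal
kernel ships.

## Rewiring

The rewiring stage repeatedly links "the two spatially closest patches in
different components". The order in which component pairs are visited is
genuinely open; we resolve it by always adding the *globally* minimal
inter-component distance (Kruskal's rule), breaking exact distance ties by
the lowest endpoint index pair. This choice satisfies both requirements —
closest patches, minimum number of links (one fewer than the number of
components) — and has a sharp consequence used heavily in testing:
rewiring an edgeless layout reproduces the Euclidean minimum spanning
tree exactly, for which an independent oracle (Prim's algorithm) is easy
to write. The deterministic-filtering limit `μ → -∞` therefore produces
MST-like approximate planar networks.

## Numerical and edge-case decisions

* **Deterministic filtering** removes a link iff `P(D) > 0.5`,
  i.e. `D > μ`; a link at exactly `D = μ` is retained. The model only
  defines the extreme limit; thresholding at the sigmoid midpoint is the
  natural finite-parameter version, and the retained boundary case is a
  documented convention rather than a claim.
* **Coincident patches are rejected** (`validate_layout()` errors):
  `W(0)` is undefined, and under continuous uniform sampling duplicates
  are measure-zero, so failing loudly beats silently clamping.
* **Reproducibility.** One master seed drives named sub-streams (layout,
  filtering, per-replicate epidemics, per-grid-point sweeps) via a small
  integer mixer, so stages can be varied independently. Filtering draws
  its uniforms in canonical edge order (sorted endpoint pairs), making
  results independent of the graph library's edge iteration order and
  giving common random numbers across calls: with a shared seed, raising
  `μ` never removes a link that survived at smaller `μ`.
* **Sigmoid saturation.** `P(D)` is strictly increasing mathematically,
  but in double precision it saturates to exactly 0 or 1 when
  `|λ(D-μ)|` exceeds ≈ 37 (relevant at `λ = 30`); tests therefore demand
  strict monotonicity only away from the saturated tails.
* **Modularity.** Only the Q measure is fixed by the definition; the
  partition comes from greedy agglomerative maximization
  (`igraph::cluster_fast_greedy`), recorded in the output as
  `community_algorithm` so alternates can be swapped. We cut the merge
  dendrogram ourselves, preferring the coarsest partition within 1e-12 of
  the maximum: floating-point noise in the merge sequence otherwise
  selects spurious splits on degenerate graphs (a complete graph, a
  single edge), whose correct Q is 0 under the one-community partition.
* **Metrics are topological.** Clustering, modularity and diameter are
  computed on the binarized graph — their definitions here (probability
  that two patches sharing a neighbour are connected; longest shortest
  path in hops) do not involve weights — so they are invariant to weight
  rescaling. Degree-<2 nodes contribute 0 to average clustering (the
  common library convention).
* **Best-fit ties** in the parameter sweep go to the earliest grid row
  (`L`, then `μ`, then `λ` order); the fit minimizes the *absolute*
  deviation from the target metric, recorded as such in the result.

## The epidemic model

Individuals are placed uniformly at random over patches, with one
initially infectious individual per 100 (1%) by default. Each timestep is
synchronous:

1. every individual stays with probability `p_stay` or moves to a
   neighbouring patch with probability proportional to link weight;
2. each individual infectious *at the start of the timestep* infects each
   co-located susceptible independently with probability `π`, so a
   susceptible sharing a patch with `k` infectious individuals escapes
   with probability `(1-π)^k`;
3. each start-of-step infectious individual recovers (with permanent
   immunity) with probability `ρ`.

The move → transmit → recover order, with both transmission and recovery
evaluated against start-of-step status, prevents same-step transmission
chains; newly infected individuals neither transmit nor recover in the
step they are infected. Contact is pure co-location — all individuals on
a patch are mutual contacts — since no within-patch social structure is
modelled. There is no demography and no reinfection. In the single-patch
limit the model is exactly a Reed–Frost chain-binomial, which the test
suite exploits (expected new infections `S·(1-(1-π)^I)`).

The reported time series is the percentage *currently infectious*,
`100·I(t)/n`; cumulative incidence `100·(I(t)+R(t))/n` is emitted
alongside for analyses that need ever-infected counts.

`run_replicates()` draws a **fresh network per replicate** when given
generation parameters — the scenario of interest is usually a landscape
type, i.e. a population of networks, not one realization — and reuses a
fixed network when given one, covering the other reading.

## What the synthetic experiments do and do not show

The package's tests and the acceptance script run entirely on
self-generated data, chosen to mirror the reference study conditions:

* the benchmarking sweep uses the full grid `A = 25`,
  `L ∈ {5,10,15,20,25,30}`, `μ ∈ {0.1,2,5,7,10}`,
  `λ ∈ {0.001,0.1,0.15,0.35,0.4,0.75,1.25,5,30}` (270 combinations, one
  network each) with 15 replicates at each best fit; the fitting target
  is a network the generator itself produced from grid-interior
  parameters (`L = 10, μ = 5, λ = 0.75, N = 30`), so the experiment
  measures *self-recovery*: the mean absolute replicate deviation per
  metric must fall well inside the across-grid spread of that metric;
* the epidemic contrast uses 20-patch networks, 100 individuals,
  `p_s = 0.5, π = 0.05, ρ = 0.01`, 500 timesteps and 30 replicates per
  scenario, comparing a square well-connected landscape
  (`L = 5, λ = 0.001`) with an elongated strongly filtered one
  (`L = 50, λ = 30`): the former yields larger outbreak peaks, the latter
  larger median diameter and clustering (50 networks per scenario);
* stochastic filtering is calibrated against the exact sum-of-Bernoullis
  law for retained-link counts (500 seeded repetitions on a fixed
  20-patch layout at `λ ∈ {0.001, 0.35, 30}`), and small-graph metrics
  against exhaustive oracles (`N ≤ 8–10`).

Passing these checks shows the machinery is internally correct and that
the qualitative landscape-epidemic interactions are reproduced at this
scale. It does not validate the model against real habitats: uniform
coordinates have no spatial aggregation (no point-process clustering),
attributes play no role in link formation, link weights are not informed
by observed movement or gene flow, and the co-location contact model
ignores within-patch social structure. Fitting to empirical targets goes
through `fit_network()` with any connected graph carrying coordinates.

## Known limitations

Directed links (e.g. downhill-biased movement), non-uniform point
processes, weighted metric variants, demography and SEIR-type extensions
are out of scope. Modularity of the detected partition is a lower bound
on the optimum (greedy agglomeration); diameter requires a connected
graph, with `largest_component()` as the documented escape hatch. The
sweep is a plain grid search by design — it reproduces a benchmarking
procedure, not a general-purpose optimizer.
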