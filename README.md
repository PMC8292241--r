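# habnet

Spatially explicit generative models of **animal habitat networks**, with
structural benchmarking and an agent-based epidemic simulation.

Habitat networks describe where animals of a focal species *can* move:
nodes are habitat patches anchored in a landscape, links denote potential
movement between patches. Classical random geometric graphs connect every
pair of points closer than a hard threshold, which overstates spatial
clustering — real landscapes contain barriers that sever nearby patches
and corridors that join distant ones, and landscapes themselves range from
open plains to narrow valleys. `habnet` generates networks that capture
this variability, for ecologists and epidemiological modellers who want to
ask how habitat geometry and connectivity shape population processes.

## The model

A rectangular landscape has area `A` and side length `L` (extent
`[0, L] × [0, A/L]`; large `L` gives elongated, valley-like shapes).
`N` patch coordinates are drawn uniformly on the landscape (or supplied by
the user). Generation then proceeds in three stages:

1. **Complete weighted graph.** Every pair `(i, j)` is linked with weight
   `W(D_ij) = D_ij⁻¹`, the reciprocal of the Euclidean distance.
2. **Sigmoidal link filtering.** Each link is independently removed with
   probability

   `P(D_ij) = [1 + exp(−λ (D_ij − μ))]⁻¹`

   where `λ > 0` sets the steepness of the distance dependence and `μ` is
   the critical distance at which removal probability crosses ½. Small `λ`
   makes link presence nearly independent of distance; large `λ`
   approaches a hard distance threshold at `μ`. A deterministic mode
   removes exactly the links longer than `μ`.
3. **Rewiring (optional).** If a connected habitat is required, the two
   spatially closest patches in different components are linked repeatedly
   until one component remains — the minimum possible number of added
   links. Rewired links get weight `D⁻η` (`η ≥ 1`, default 1); starting
   from an edgeless graph this procedure yields exactly the Euclidean
   minimum spanning tree.

On generated (or imported) networks the package computes the average
clustering coefficient, Newman modularity (greedy agglomerative
partition), and hop-count diameter; a grid-sweep engine finds, for each
metric, the `(L, μ, λ)` combination whose networks best approximate a
target network's value. An agent-based SIR simulation moves individuals
across patches (stay with probability `p_s`, otherwise step to a
neighbour with probability proportional to link weight), transmits
infection between co-located individuals with per-contact probability
`π`, and recovers them with probability `ρ`.

## Worked example

```r
library(habnet)

params <- ahn_params(A = 25, L = 5, N = 30, lambda = 0.35, mu = 5, seed = 42)
net <- generate_network(params)
network_metrics(net)
#>   n_nodes n_edges clustering modularity diameter community_algorithm
#> 1      30     284  0.6689451 0.07734081        2         fast_greedy
```

On a square 5 × 5 landscape with a gentle distance penalty
(`λ = 0.35, μ = 5`), most of the 435 possible links survive filtering
(284 here), so the network is dense: any patch is reachable within two
hops (diameter 2), two-thirds of neighbour pairs are themselves connected
(clustering 0.67), and there is little community structure
(modularity 0.08).

Epidemic on that kind of landscape, averaging 10 replicate simulations,
each on a freshly generated 20-patch network:

```r
scenario <- ahn_params(A = 25, L = 5, N = 20, lambda = 0.001, mu = 5)
res <- run_replicates(scenario, epidemic_params(n_reps = 10), seed = 1)
res$summary[res$summary$t %in% c(50, 100, 200, 500), ]
#>       t mean_pct_infected sd_pct_infected mean_pct_ever_infected
#> 51   50              76.4            8.26                   99.9
#> 101 100              48.9            4.61                  100.0
#> 201 200              16.1            5.15                  100.0
#> 501 500               0.6            0.70                  100.0
```

Starting from a single infectious individual (1% of the population), the
infection sweeps through essentially the whole population (mean peak 82%
infectious around t ≈ 40–50) and then burns out as individuals recover.
Repeating this with an elongated landscape and steep filtering
(`L = 50, lambda = 30`) gives chain-like networks with larger diameter
and smaller outbreaks — the contrast quantified by the acceptance script
below.

A command-line front end wrapping these functions is installed at
`system.file("cli", "habnet.R", package = "habnet")` with subcommands
`generate`, `metrics`, `sweep` and `epidemic`.

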