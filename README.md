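# hypercoop

Evolutionary game dynamics on scale-free networks with a latent hyperbolic
geometry: do cooperators survive social dilemmas by self-organizing into
*metric clusters* — contiguous arcs of the hidden similarity space — the way
they form spatial clusters on lattices?

## The model in brief

**Networks.** Nodes live on a hyperbolic disc of radius
`R = 2·ln[2·T̄·N / (k̄·sin(T̄π)) · ((γ−1)/(γ−2))²]`: a radial coordinate
encodes popularity (expected degree, power-law exponent `γ`), a uniform
angular coordinate encodes similarity. Pairs connect independently with the
Fermi-like probability `p(x) = 1/(1 + exp((x − R)/(2T̄)))` of their
hyperbolic distance `x`. The graph temperature `T̄ ∈ (0, 1)` tunes the mean
local clustering (low `T̄` → strongly metric, highly clustered networks);
`calibrate_temperature()` inverts that relationship empirically.

**Games.** 2x2 social dilemmas normalised to reward 1 / punishment 0 and
parameterised by the temptation `T` and sucker's payoff `S` (prisoner's
dilemma: `T > 1`, `S < 0`). Each synchronous generation, every node plays
all neighbours, accumulates payoffs, then imitates a random neighbour with
the Fermi probability `1/(1 + exp(−(π_j − π_i)/K))`, `K = 0.5`. Dynamics
run on the giant component; the generation loop is a C++ kernel driven by
R's RNG, so `set.seed()` reproduces entire trajectories bit-for-bit.

**Seeding and metrics.** Initial cooperators can be placed at random, on
hubs (degree-preferential), as one or several metric clusters (arcs of the
similarity circle), or as a topologically connected cluster with no metric
constraint. The angular Kolmogorov–Smirnov statistic
`ρ̄ = c·ρ_C + (1−c)·ρ_D` measures how far cooperators/defectors deviate
from uniform over the circle, and `intercluster_link_fraction()` counts the
scarce links through which defectors can invade a cluster. Experiment
drivers (`ts_phase_sweep()`, `gamma_clustering_sweep()`,
`cluster_scaling_experiment()`, `intercluster_link_experiment()`) orchestrate
the standard studies with per-cell derived seeds.

## Worked example

```r
library(hypercoop)

# a strongly metric scale-free network
params <- network_params(n_nodes = 2000, gamma = 2.6, kbar_target = 6,
                         temperature = 0.3, seed = 4)
g <- generate_network(params)
mean_local_clustering(g)
#> [1] 0.6576671
2 * igraph::ecount(g) / igraph::vcount(g)
#> [1] 6.142
degree_sequence_stats(g)$tail_exponent   # Hill estimate of gamma
#> [1] 2.571019
```

Calibrate the temperature for a target clustering, then contrast metric
against random seeding in a harsh prisoner's dilemma (`T = 1.5`,
`S = −0.5`) on fresh networks with `N = 5000`, `γ = 2.9`:

```r
np <- network_params(5000, 2.9, 6)
set.seed(1)
np$temperature <- calibrate_temperature(0.6, np, pilot_realizations = 2)
np$temperature
#> [1] 0.33125

pd  <- game_params(temptation = 1.5, sucker = -0.5, noise = 0.5)
met <- final_cooperation(np, pd, seed_spec("metric_cluster"),
                         horizon = 2e4, n_realizations = 10, root_seed = 11)
rnd <- final_cooperation(np, pd, seed_spec("random"),
                         horizon = 2e4, n_realizations = 10, root_seed = 12)
c(metric = met$mean, random = rnd$mean)
#>    metric    random
#> 0.1812038 0.0000000
round(met$finals, 3)
#>  [1] 0.011 0.363 0.446 0.008 0.476 0.000 0.387 0.000 0.039 0.083
```

Randomly seeded cooperation is wiped out in all ten realizations; seeded as
a single metric cluster it survives to a substantial stationary density in
about half of them. The shield is the scarcity of links leaving the
cluster:

```r
set.seed(2)
h <- giant_component(generate_network(np))
intercluster_link_fraction(h, seed_metric_cluster(h, 0.5))
#> [1] 0.02922184
```

— under 3% of all edges connect the half-network metric cluster to the
rest, versus ~50% for a random half.

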