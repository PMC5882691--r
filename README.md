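# vasculonet

Quantitative analysis of forming vascular networks in binary image time
series.

During early vasculogenesis, scattered endothelial-cell clusters grow and
fuse into a connected capillary plexus. Given a thresholded (binary)
time-lapse of that process, `vasculonet` measures how the pattern
assembles and what topology it assembles into — the toolkit a
quantitative biologist or biophysicist needs to compare, for example,
untreated embryos against embryos exposed to an anti-VEGF agent such as
bevacizumab, whose networks end up denser and more lattice-like instead
of tree-like.

The package covers three layers of analysis:

* **Cluster statistics and percolation.** Vessel density
  ρ(t) = (vessel area)/(total area), cluster counts and area
  distributions under 8-connected labelling with a physical area filter,
  and the largest-cluster density ρ^LC(t) whose abrupt rise marks the
  percolation-like transition to a spanning network. Box-counting
  fractal dimension D_f over a geometric box-size series.
* **Bifurcation-network topology.** Skeletonization (Guo–Hall thinning)
  and conversion to a graph with bifurcations/endpoints as nodes and
  vessel chords as edges, then the planar-network metric suite:
  degree distribution P(k), mean degree ⟨k⟩ = 2n_ℓ/N, gamma index
  γ = n_ℓ/3(N−2), average shortest path ⟨L⟩, treeness
  ϕ = L_Tree/⟨L⟩ (1 for trees, 0 for all-cycle graphs), clustering
  ⟨C⟩, degree assortativity r, largest-component fraction f, and mean
  chord length ℓ; plus a two-sample KS comparison of degree samples.
* **Growth dynamics.** Nonlinear least-squares fits of the logistic
  density curve ρ(t) = [1/ρ_max + (1/ρ_0 − 1/ρ_max)e^{−ωt}]^{−1} and
  threshold-based detection of percolation onset and saturation times.

Because time-lapse movies are rarely distributed as machine-readable
data, the package includes first-class synthetic generators: logistic
density series, diffusion-limited cluster–cluster aggregation (DLCA)
patterns with D_f ≈ 1.35–1.4 at desk scale, planar vascular graphs
(tree-like vs lattice-like), and full three-stage vasculogenesis image
series with known ground-truth topology.

## Worked example

Simulate a control-like series, extract the final network, and fit the
growth curve:

```r
library(vasculonet)

cfg    <- simulation_config(seed = 1, mode = "control_like")
frames <- simulate_vasculogenesis_series(cfg)
last   <- frames[[length(frames)]]
last
#> <binary_frame> 400 x 400 px, 0.0064 mm/px, t = 15 h, density 0.0955

g <- skeleton_to_graph(skeletonize(last), prune_px = 3, node_merge_px = 3)
g
#> <vessel_graph> 90 nodes, 99 edges, mean chord 0.245 mm

round(network_metrics(g)[, c("mean_degree", "gamma", "treeness",
                             "clustering", "lcc_fraction")], 3)
#>   mean_degree gamma treeness clustering lcc_fraction
#> 1         2.2 0.375    0.257      0.115            1

s <- density_series(attr(frames, "times_h"), attr(frames, "density"))
fit_logistic(s)
#> <logistic_params> rho0 = 0.00209, rho_max = 0.1042, omega = 0.4196 /h (rss = 1.51e-08)

detect_transitions(s)
#> <transition_times> onset 3.72 h, saturation 13.3 h (plateau 0.09259)
```

Reading the output: the final frame covers 9.6 % of the field with
vessel; its bifurcation network has mean degree 2.20 and treeness 0.26 —
a mostly tree-like topology with some loops, typical of an untreated
network (an `avastin_like` series at the same seed yields ⟨k⟩ ≈ 2.6,
γ ≈ 0.44 and ϕ ≈ 0.15, the lattice-like signature). The fitted growth
rate ω ≈ 0.42 h⁻¹ recovers the generator's nominal control value, and
the density curve starts saturating late in the 15 h window.

The `analysis/` directory holds the full workflow as numbered scripts —
`01_simulate.R` (generate both groups, three seeds each),
`02_cluster_dynamics.R` (cluster statistics and percolation times),
`03_network_metrics.R` (extraction, metric evolution, group summary and
KS test), `04_growth_fit.R` (logistic fits and parameter recovery),
`05_fractal.R` (DLCA and box counting) — each writing its tables under
`results/`.

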