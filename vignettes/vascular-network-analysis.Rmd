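---
title: "Quantifying vasculogenesis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vasculogenesis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculonet)
```

## The scientific problem

During early vasculogenesis, scattered endothelial-cell (EC) clusters
migrate, grow and fuse into a connected capillary plexus. Bright-field
time-lapse imaging of this process yields, after thresholding, a sequence
of binary images in which the forming vasculature is the foreground.
`vasculonet` quantifies such sequences along three complementary axes:

1. **Binary-pattern statistics** — vessel density
   $\rho(t)$ (foreground area / image area), the number of EC clusters
   $N_c(t)$, the cluster-area distribution, and the largest-cluster
   density $\rho^{LC}(t)$, the area-based order parameter of the
   percolation-like transition from fragmented clusters to one spanning
   network. The box-counting fractal dimension $D_f$ summarizes the
   geometry of the pattern at each stage.
2. **Network topology** — the skeleton of the pattern is converted into a
   graph whose nodes are vessel bifurcations and endpoints and whose edges
   are the vessel segments (chords) between them, with the metric suite:
   degree distribution $P(k)$, mean degree
   $\langle k\rangle = \tfrac1N\sum_i k_i$, gamma index
   $\gamma = n_\ell / 3(N-2)$, average shortest path $\langle L\rangle$,
   treeness $\phi = L_{Tree}/\langle L\rangle$, mean clustering
   $\langle C\rangle$, degree assortativity $r$, and the fraction of
   nodes in the largest component $f$.
3. **Growth dynamics** — the density curve is fit with the closed-form
   solution of logistic growth,
   $$\rho(t) = \frac{1}{1/\rho_{max} + (1/\rho_0 - 1/\rho_{max})e^{-\omega t}},$$
   and the onset and saturation times of $\rho^{LC}$ are extracted.

The package targets the contrast between untreated (control) networks,
which mature into predominantly tree-like topologies, and networks formed
under anti-VEGF treatment (bevacizumab), which end up denser and more
lattice-like: higher $\gamma$ and $\langle k\rangle$, lower $\phi$,
shorter chords.

Because real embryo movies are not machine-readable inputs here, the
package ships a first-class synthetic-data generator that emulates the
statistical structure of such experiments; all tests and the acceptance
script run on synthetic data.

## The synthetic generator and what it emulates

`simulate_vasculogenesis_series()` builds a frame sequence in three
conceptual stages, mirroring early cluster appearance, percolation and
remodelling:

* A planar **target graph** is generated first
  (`generate_vascular_graph()`): points scattered with a minimum-spacing
  rule, joined by the Gabriel proximity graph (planar by construction, a
  subgraph of the Delaunay triangulation, and computable directly from
  pairwise distances — the reason it was chosen over an explicit Delaunay
  step), pruned of edges longer than twice the chord scale, capped at
  degree 4 (vessel bifurcations have at most four branches), then shaped:
  a minimum spanning tree augmented with short chords (control-like) or a
  cycle-rich subgraph thinned by non-bridge edge removal
  (treatment-like).
* Every foreground pixel of the rendered final image receives a **reveal
  rank**: node discs appear first in random order, then each vessel
  sprouts from one randomly chosen end and completes at a staggered time,
  so cluster merges are spread over the growth phase as in a percolation
  process.
* Frame $t$ shows the first $\rho(t)/\rho(t_{end})$ fraction of pixels in
  reveal order, with $\rho(t)$ a logistic curve. The frame-wise density
  therefore follows logistic growth exactly (up to pixel rounding), the
  cluster count rises while discs appear and falls as vessels fuse, and
  the final frame equals the rendered target graph — giving every series
  a known ground-truth topology for round-trip testing.

### Default study conditions

Defaults in `simulation_config()` encode the imaging conditions the
generator emulates: 6.4 µm pixels (`px_size_mm = 0.0064`), a
400 × 400 px field (≈ 6.6 mm²), 52 frames over 15 h. Growth rates are the
group-typical values 0.42 h⁻¹ (control) and 0.52 h⁻¹ (treated); the area
filter removes clusters below 1.2 × 10⁻⁴ mm².

Three generator constants were calibrated once, against the group-level
statistics the pipeline is meant to reproduce, and are not tuned per run:

* `n_seeds_clusters = 160` and a point spacing of ≈ 0.42 × the chord
  scale put the **bifurcation spacing** (the mean chord length measured
  on the extracted graph, where degree-2 points belong to edges, not to
  the node set) at ≈ 0.25–0.28 mm for `chord_scale_mm = 0.26`. Point
  spacing alone does not control this: on tree-like graphs roughly 40 %
  of raw nodes are degree-2 and dissolve into their edges, stretching the
  measured chord by about 1.8–2.5×.
* The internal mean-degree targets (2.42 control-like, 2.68
  treatment-like) sit ≈ 0.14 above the group-typical extracted values
  (2.28 / 2.54) because extraction collapses parallel vessel paths
  between the same bifurcation pair onto a single adjacency entry, which
  lowers the measured mean degree by about that amount.
* Lattice thinning removes non-bridge edges preferring endpoints that
  remain bifurcations (degree ≥ 3 after removal) and stops just *above*
  the target: random thinning decays networks into long degree-2 runs
  whose contracted mean degree overshoots well below the target.

What the generator does **not** emulate: grayscale microscope noise
beyond optional thresholding tests, illumination gradients, vessel-width
heterogeneity, cell-scale texture, and curved vessels (edges render as
straight strokes). Passing tests on synthetic data therefore validate the
measurement pipeline — extraction fidelity, metric correctness, fit
behaviour — not the biology of any particular experiment.

## Graph extraction

`skeletonize()` applies Guo–Hall thinning (topology-preserving, two
sub-iteration parallel scheme). Zhang–Suen thinning was rejected after it
erased entire 2-px-wide diagonal strips — a known failure mode of that
scheme that deleted whole vessel arms.

`skeleton_to_graph()` classifies skeleton pixels by 8-neighbour count:
junction pixels (≥ 3 neighbours) cluster into nodes at their centroid,
endpoint pixels become degree-1 nodes, degree-2 pixels belong to edge
polylines. Chord length accumulates 1 per axial and $\sqrt2$ per diagonal
step, times the pixel size. Post-processing, in order: merge nodes closer
than `node_merge_px` (thick junctions skeletonize into nearby clusters;
use the vessel width when known), prune terminal spurs shorter than
`prune_px` (default 3 px — well below the ≈ 40 px chord scale, so real
capillaries survive), dissolve the degree-2 nodes those steps leave,
discard self-loops, collapse parallel paths (shortest length kept,
multiplicity in `n_parallel`), and split any node still above degree 4
with an extraction warning. Components with no node pixel (pure pixel
cycles) get a single anchor node so component counts survive extraction.

On clean renders of 50-node trees the render → skeletonize → extract
round trip recovers the contracted ground truth exactly (100 % of node
degrees on the tested seeds; the acceptance suite requires ≥ 90 %).

## Metric conventions

* $P(k)$ is a probability mass function (the per-degree node fraction);
  an upper-cumulative variant is available via `cumulative = TRUE`.
* $\gamma$ uses the planar bound $3(N-2)$ and is not clamped; values
  above 1 trigger a planarity warning.
* $\langle L\rangle$, $\phi$ and $r$ are computed on the largest
  connected component (distances between disconnected nodes diverge);
  $\langle k\rangle$, $\gamma$, $\langle C\rangle$ and $P(k)$ on the full
  graph.
* **Treeness** interprets "the graph without closed circuits" as the
  pendant forest: the edges outside the 2-core of the largest component.
  $L_{Tree}$ is the pair-count-weighted mean path length over pendant
  forest components, and $\phi = L_{Tree}/\langle L\rangle$ clamped to
  $[0,1]$. This is the only reading that satisfies both endpoints —
  $\phi = 1$ on trees (the pendant forest is the whole graph) and
  $\phi = 0$ on pure cycles (the forest is empty); a spanning-tree
  reading would exceed 1 on cyclic graphs.
* **Assortativity** is the Pearson correlation of degrees over the
  symmetrized edge-end list. This is the only moment convention giving
  $r \in [-1, 1]$ with $r = -1$ on stars; degree-regular graphs return
  `NA` flagged `defined = FALSE` rather than an error.
* Nodes with $k < 2$ contribute 0 to $\langle C\rangle$.

Every metric is checked against an independent brute-force oracle
(Floyd–Warshall distances, leaf-stripping 2-core, direct triangle and
edge-end enumeration) on hundreds of random graphs of ≤ 7 nodes.

## Numerical choices

* **Box counting** uses the geometric size series 2, 4, …, 128 plus the
  upper bound itself (default 200 px), grids anchored at the image
  origin, and $D_f = -$slope of the least-squares log–log line.
  Multi-offset averaging is available (`offsets > 0`) but off by
  default — it changes the DLCA estimate by < 0.01. Note the series end
  points matter: on a filled 512² frame the non-divisor 200 px box gives
  $D_f = 1.96$ rather than 2.00 exactly.
* **DLCA** (`simulate_dlca()`) implements lattice cluster–cluster
  aggregation: uniform seeding, per-sweep move probability
  $\propto s^{-1/2}$ for a cluster of $s$ particles, reflecting
  boundaries, irreversible merging on 8-connectivity contact. The
  C++ kernel uses R's RNG, so `set.seed` governs it. At 4000 particles
  on a 512² lattice the measured box dimension is ≈ 1.34–1.39: the
  mass–radius dimension of the growing clusters rises with mass
  (0.8 → 1.1 → 1.35 over the accessible range) toward the asymptotic
  ≈ 1.44 of 2-D DLCA, and the 2–200 px box range additionally spans the
  1-px arm-thickness scale (local slope ≈ 1) and the saturation scale
  (local slope < 1), both of which pull the global fit below the
  mid-range value. Early lattice CCA studies report 1.38 ± 0.06 at
  comparable masses, so the simulator is within the canonical family;
  reaching ≈ 1.45–1.5 by this estimator would need far larger aggregates
  than the simulated conditions provide.
* **Logistic fitting** uses bounded Levenberg–Marquardt
  (`minpack.lm::nlsLM`) with unweighted least squares, initialised at the
  first value (floored at $10^{-3}$), the series maximum and 0.5 h⁻¹,
  plus four deterministic restarts scaling the initial rate by 0.15–6;
  the best of the converged fits by RSS wins. Standard errors come from
  the local curvature. Flat series and universal non-convergence raise a
  typed fit-failure error carrying the per-restart diagnostics.
* **Transition detection** uses relative thresholds: the plateau is the
  mean of the final 10 % of samples; onset is the earliest linearly
  interpolated crossing of 10 % of the plateau after which the series
  stays above half that level (the guard rejects pre-percolation
  flicker); saturation is the earliest crossing of 95 %. Curvature-based
  definitions were rejected as too noise-sensitive for short series; the
  thresholds are arguments.
* **Thresholding** defaults to Otsu with darker-than-threshold foreground
  (bright-field vessels are dark); `dark_vessels = FALSE` inverts. A
  manual level outside the observed intensity range is accepted with a
  warning — useful for degenerate test images — rather than rejected.

## Problem sizes

The shipped tests and scripts use deliberately modest sizes: series of
2–52 frames at 200–400 px, graphs of 30–160 nodes, 100-replicate fit
recovery, three DLCA aggregates of 4000 particles. These sizes were
chosen so the full suite exercises every pipeline stage — including the
slowest, single-aggregate DLCA — while each individual check stays in
seconds; they are stated here so analyses can be scaled up deliberately
rather than by accident.

## Known limitations

* The extractor measures bifurcation-level topology only; degree-2 nodes
  of a drawing are invisible to it by design, so degree distributions
  from this pipeline have $P(2) = 0$ and are comparable between runs of
  this pipeline, not directly with tools that keep degree-2 junctions.
* Parallel vessel paths between the same two bifurcations enter the
  adjacency once; dense lattice-like networks therefore read ≈ 0.1 lower
  in $\langle k\rangle$ than their drawn multigraph.
* The generator's vessels are straight; chord length equals the Euclidean
  node distance, so the `chord_length_mm ≥ node distance` invariant holds
  with equality and curvature effects are untested.
* `fit_logistic` assumes a growing, saturating series; it will fit a
  decaying series badly rather than refusing.
* The DLCA box dimension under-reads its asymptotic value at desk scale,
  as analysed above.
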