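#' Degree distribution P(k)
#'
#' Probability mass function of node degrees: P(k) = N(k)/N, the number of
#' nodes with k neighbours over the total number of nodes.  Isolated nodes
#' contribute to P(0).  Set `cumulative = TRUE` for the survival-function
#' variant (fraction of nodes with degree >= k).
#'
#' @param graph a [vessel_graph()] or igraph object with at least 1 node.
#' @param cumulative return the upper cumulative variant instead of the
#'   mass function.
#' @return named numeric vector, names are degrees; sums to 1 when
#'   `cumulative = FALSE`.
#' @export
degree_distribution <- function(graph, cumulative = FALSE) {
  ig <- as_igraph(graph)
  n <- igraph::vcount(ig)
  if (n == 0) stop_invalid("empty graph")
  k <- igraph::degree(ig)
  tab <- table(k) / n
  p <- setNames(as.numeric(tab), names(tab))
  if (cumulative) {
    p <- rev(cumsum(rev(p)))
  }
  p
}

#' Mean degree
#'
#' Average number of neighbours per node; equals `2 * n_links / N` by the
#' handshake identity.
#'
#' @param graph a [vessel_graph()] or igraph object with at least 1 node.
#' @return mean degree.
#' @export
mean_degree <- function(graph) {
  ig <- as_igraph(graph)
  if (igraph::vcount(ig) == 0) stop_invalid("empty graph")
  mean(igraph::degree(ig))
}

#' Gamma connectivity index
#'
#' Link density of a planar network: the number of links over the planar
#' maximum `3 (N - 2)`.  Zero means no connections, one a maximally
#' connected planar network.  Values above 1 are possible only for
#' non-planar input and raise a planarity warning; the value is not
#' clamped.
#'
#' @param graph a [vessel_graph()] or igraph object with at least 3 nodes.
#' @return gamma index.
#' @export
gamma_index <- function(graph) {
  ig <- as_igraph(graph)
  n <- igraph::vcount(ig)
  if (n < 3) stop_undefined("gamma index requires at least 3 nodes")
  gam <- igraph::ecount(ig) / (3 * (n - 2))
  if (gam > 1) {
    warning("gamma index exceeds 1: the graph cannot be planar", call. = FALSE)
  }
  gam
}

largest_component <- function(ig) {
  comp <- igraph::components(ig)
  igraph::induced_subgraph(ig, which(comp$membership == which.max(comp$csize)))
}

#' Average shortest path length
#'
#' Mean unweighted shortest-path distance over all ordered node pairs of
#' the largest connected component (restricting to the largest component
#' avoids the divergence of distances between disconnected nodes).
#'
#' @param graph a [vessel_graph()] or igraph object whose largest component
#'   has at least 2 nodes.
#' @param scope currently only `"largest_component"`.
#' @return average shortest path length (in links).
#' @export
avg_shortest_path <- function(graph, scope = "largest_component") {
  scope <- match.arg(scope, "largest_component")
  ig <- as_igraph(graph)
  lc <- largest_component(ig)
  if (igraph::vcount(lc) < 2) {
    stop_undefined("largest component has fewer than 2 nodes")
  }
  igraph::mean_distance(lc)
}

#' Treeness index phi
#'
#' Quantifies how much of the network's path structure lives in acyclic
#' (branch) parts: `phi = L_Tree / <L>`, where `<L>` is the average
#' shortest path length of the largest component and `L_Tree` is the
#' pair-count-weighted average path length over the components of the
#' pendant forest — the part of the graph outside its 2-core, i.e. the
#' graph without closed circuits.  A tree gives phi = 1, a graph that is
#' all closed paths gives phi = 0; the ratio is clamped to \[0, 1\].
#'
#' @param graph a [vessel_graph()] or igraph object whose largest component
#'   has at least 2 nodes.
#' @return treeness in \[0, 1\].
#' @export
treeness <- function(graph) {
  ig <- as_igraph(graph)
  lc <- largest_component(ig)
  if (igraph::vcount(lc) < 2) {
    stop_undefined("largest component has fewer than 2 nodes")
  }
  L <- igraph::mean_distance(lc)
  core <- igraph::coreness(lc)
  el <- igraph::as_edgelist(lc, names = FALSE)
  pendant <- core[el[, 1]] < 2 | core[el[, 2]] < 2
  if (!any(pendant)) return(0)
  pf <- igraph::subgraph_from_edges(lc, which(pendant), delete.vertices = TRUE)
  comp <- igraph::components(pf)
  tot_d <- 0; tot_p <- 0
  for (ci in seq_len(comp$no)) {
    if (comp$csize[ci] < 2) next
    sub <- igraph::induced_subgraph(pf, which(comp$membership == ci))
    D <- igraph::distances(sub)
    tot_d <- tot_d + sum(D[upper.tri(D)])
    tot_p <- tot_p + sum(upper.tri(D))
  }
  if (tot_p == 0) return(0)
  min(1, max(0, (tot_d / tot_p) / L))
}

#' Mean clustering coefficient
#'
#' Average of the local clustering coefficient `2 e_i / (k_i (k_i - 1))`
#' over all nodes, where `e_i` counts edges among the neighbours of node
#' i; nodes with fewer than 2 neighbours contribute 0.
#'
#' @param graph a [vessel_graph()] or igraph object with at least 1 node.
#' @return mean clustering coefficient in \[0, 1\].
#' @export
clustering_coefficient <- function(graph) {
  ig <- as_igraph(graph)
  n <- igraph::vcount(ig)
  if (n == 0) stop_invalid("empty graph")
  k <- igraph::degree(ig)
  tri <- igraph::count_triangles(ig)
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  mean(ci)
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees at the two ends of each edge, over
#' the symmetrized edge list (each edge counted in both directions).
#' Negative values indicate disassortative (e.g. star-like) structure;
#' `r = -1` for a star.  When the edge-end degree variance is zero (a
#' degree-regular graph) the coefficient is undefined and `NA` is
#' returned with attribute `defined = FALSE` rather than an error.
#'
#' @param graph a [vessel_graph()] or igraph object with at least 2 edges.
#' @return assortativity in \[-1, 1\], or `NA` (attribute `defined`) for
#'   degree-regular graphs.
#' @export
assortativity <- function(graph) {
  ig <- as_igraph(graph)
  if (igraph::ecount(ig) < 2) stop_invalid("need at least 2 edges")
  el <- igraph::as_edgelist(ig, names = FALSE)
  k <- igraph::degree(ig)
  x <- c(k[el[, 1]], k[el[, 2]])
  y <- c(k[el[, 2]], k[el[, 1]])
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure(cor(x, y), defined = TRUE)
}

#' Fraction of nodes in the largest connected component
#'
#' The node-based percolation order parameter f: the share of all nodes
#' belonging to the largest connected cluster, reaching its maximum f = 1
#' when the network is fully connected.
#'
#' @param graph a [vessel_graph()] or igraph object with at least 1 node.
#' @return fraction in (0, 1\].
#' @export
largest_component_fraction <- function(graph) {
  ig <- as_igraph(graph)
  n <- igraph::vcount(ig)
  if (n == 0) stop_invalid("empty graph")
  max(igraph::components(ig)$csize) / n
}

#' Kolmogorov-Smirnov comparison of two degree samples
#'
#' Two-sample KS test on node-degree samples, as used to compare the
#' degree distributions of control and treated networks.
#'
#' @param sample_a,sample_b non-empty numeric vectors of node degrees.
#' @param alpha significance level (default 0.05).
#' @return list with `p_value`, `statistic` and `significant`.
#' @export
ks_compare_degrees <- function(sample_a, sample_b, alpha = 0.05) {
  if (!length(sample_a) || !length(sample_b)) {
    stop_invalid("degree samples must be non-empty")
  }
  kt <- suppressWarnings(ks.test(sample_a, sample_b))
  list(p_value = unname(kt$p.value), statistic = unname(kt$statistic),
       significant = unname(kt$p.value) < alpha)
}

#' Full metric record for one network
#'
#' Computes the whole per-frame metric suite: node and link counts, degree
#' fractions P(1)..P(4), mean degree, gamma index, average shortest path,
#' treeness, clustering, assortativity and the largest-component node
#' fraction.  Mean degree, gamma, clustering and P(k) use the full graph;
#' average path length, treeness and assortativity the largest component
#' (metrics whose preconditions fail on a given frame are `NA`).
#'
#' @param graph a [vessel_graph()] or igraph object.
#' @param t_h optional timestamp copied into the record.
#' @return one-row data.frame.
#' @export
network_metrics <- function(graph, t_h = NA_real_) {
  ig <- as_igraph(graph)
  n <- igraph::vcount(ig)
  nl <- igraph::ecount(ig)
  pk <- if (n > 0) degree_distribution(ig) else numeric(0)
  pget <- function(k) if (as.character(k) %in% names(pk)) pk[[as.character(k)]] else 0
  safe <- function(expr) tryCatch(suppressWarnings(expr), error = function(e) NA_real_)
  lc <- if (n > 0) largest_component(ig) else ig
  data.frame(
    t_h = t_h, n_nodes = n, n_links = nl,
    mean_degree = safe(mean_degree(ig)),
    gamma = safe(gamma_index(ig)),
    avg_path = safe(avg_shortest_path(ig)),
    treeness = safe(treeness(ig)),
    clustering = safe(clustering_coefficient(ig)),
    assortativity = safe(as.numeric(assortativity(lc))),
    lcc_fraction = safe(largest_component_fraction(ig)),
    p1 = pget(1), p2 = pget(2), p3 = pget(3), p4 = pget(4))
}
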