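#' Generate a planar synthetic vascular graph
#'
#' Scatters points in the region with a minimum spacing of about the chord
#' scale (dart throwing), builds a planar proximity graph — the Gabriel
#' graph, a planar subgraph of the Delaunay triangulation computable
#' directly from pairwise distances — pruned of edges longer than
#' `2 * chord_scale_mm`, and then shapes the topology:
#'
#' * `mode = "tree"`: the minimum spanning tree (by edge length).  With
#'   `target_degree > 2` the tree is augmented with the shortest available
#'   chords until the mean degree reaches the target, giving the
#'   mostly-tree-with-some-loops morphology of untreated vascular networks.
#' * `mode = "lattice"`: the full pruned proximity graph thinned by random
#'   non-bridge edge removal until the mean degree falls to
#'   `target_degree`, giving the cycle-rich lattice-like morphology seen
#'   under anti-VEGF treatment.
#'
#' All node degrees are capped at 4 (vessel bifurcations have at most four
#' branches) by removing the longest incident edges, preferring removals
#' that keep the graph connected.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param mode `"tree"` or `"lattice"`.
#' @param region_size_mm numeric pair, region extent in mm.
#' @param chord_scale_mm target mean chord length in mm, i.e. the spacing
#'   between consecutive bifurcations (what [mean_chord_length()] measures
#'   on the extracted, degree-2-contracted graph).
#' @param seed integer seed.
#' @param target_degree desired mean degree; `NULL` gives a pure spanning
#'   tree in tree mode and 2.55 in lattice mode.
#' @param degree_scope how `target_degree` is measured: `"raw"` on the
#'   generated node set, or `"contracted"` on the bifurcation-level graph
#'   with degree-2 nodes dissolved into their edges — the form a
#'   skeleton-graph extractor recovers, hence the scope used when
#'   calibrating against extracted mean degrees.
#' @return a [vessel_graph()].
#' @export
generate_vascular_graph <- function(n_nodes, mode = c("tree", "lattice"),
                                    region_size_mm = c(2.56, 2.56),
                                    chord_scale_mm = 0.26, seed = 1,
                                    target_degree = NULL,
                                    degree_scope = c("raw", "contracted")) {
  mode <- match.arg(mode)
  degree_scope <- match.arg(degree_scope)
  if (n_nodes < 2) stop_invalid("n_nodes must be >= 2")
  region_size_mm <- rep(region_size_mm, length.out = 2)
  if (is.null(target_degree)) {
    target_degree <- if (mode == "lattice") 2.55 else 2
  }
  withr::with_seed(seed, {
    # chord_scale_mm targets the *bifurcation* spacing (the chord length an
    # extractor measures after dissolving degree-2 points, which stretches
    # raw point spacing by roughly 1.8x on tree-like graphs), so points are
    # scattered at about half the chord scale; the spacing also yields to
    # the densest packing the region supports (random sequential adsorption
    # saturates near 0.7 * area / d^2 points at spacing d) but never drops
    # below 20% of the chord scale, so truly over-dense requests raise a
    # capacity error
    min_dist <- max(0.20 * chord_scale_mm,
                    min(0.42 * chord_scale_mm,
                        0.72 * sqrt(prod(region_size_mm) / n_nodes)))
    pts <- scatter_min_spacing(n_nodes, region_size_mm, min_dist = min_dist)
    ed <- gabriel_edges(pts, max_len = 2 * chord_scale_mm)
    ed <- connect_components(pts, ed)
    ed <- cap_degrees(ed, n_nodes, kmax = 4L)
    mdeg <- function(e) {
      if (degree_scope == "raw") return(2 * nrow(e) / n_nodes)
      contracted_mean_degree(e, n_nodes)
    }
    if (mode == "tree") {
      keep <- mst_edges(ed, n_nodes)
      tree <- ed[keep, , drop = FALSE]
      if (target_degree > 2) {
        pool <- ed[!keep, , drop = FALSE]
        pool <- pool[order(pool$len), , drop = FALSE]
        deg <- tabulate(c(tree$from, tree$to), nbins = n_nodes)
        for (i in seq_len(nrow(pool))) {
          if (mdeg(tree) >= target_degree) break
          a <- pool$from[i]; b <- pool$to[i]
          if (deg[a] < 4 && deg[b] < 4) {
            tree <- rbind(tree, pool[i, ])
            deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
          }
        }
      }
      ed <- tree
    } else {
      ed <- thin_to_degree(ed, n_nodes, target_degree, mdeg)
    }
    vessel_graph(
      nodes = data.frame(id = seq_len(n_nodes), x_mm = pts[, 1], y_mm = pts[, 2]),
      edges = data.frame(from = ed$from, to = ed$to, chord_length_mm = ed$len))
  })
}

# dart-throwing point scatter with a hard minimum spacing
scatter_min_spacing <- function(n, region, min_dist) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 400L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop_capacity(sprintf(
        "could not place %d points with spacing %.3g mm in a %.3g x %.3g mm region",
        n, min_dist, region[1], region[2]))
    }
    cand <- runif(2) * region
    if (placed > 0) {
      d2 <- (pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_dist^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- cand
  }
  pts
}

# Gabriel graph edges among candidate pairs shorter than max_len:
# (i, j) is an edge iff no third point lies inside the circle with
# diameter ij
gabriel_edges <- function(pts, max_len = Inf) {
  n <- nrow(pts)
  D2 <- as.matrix(stats::dist(pts))^2
  pairs <- which(upper.tri(D2) & D2 <= max_len^2, arr.ind = TRUE)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    mid <- (pts[i, ] + pts[j, ]) / 2
    r2 <- D2[i, j] / 4
    d2 <- (pts[, 1] - mid[1])^2 + (pts[, 2] - mid[2])^2
    d2[c(i, j)] <- Inf
    keep[k] <- all(d2 >= r2 - 1e-12)
  }
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(from = pairs[, 1], to = pairs[, 2],
             len = sqrt(D2[pairs]))
}

edges_igraph <- function(ed, n) {
  igraph::graph_from_data_frame(
    data.frame(from = ed$from, to = ed$to),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}

# add nearest-pair bridges until the edge set is connected
connect_components <- function(pts, ed) {
  n <- nrow(pts)
  repeat {
    comp <- igraph::components(edges_igraph(ed, n))
    if (comp$no <= 1) return(ed)
    # bridge the first component to its nearest outside point pair
    in1 <- which(comp$membership == 1)
    out1 <- which(comp$membership != 1)
    D <- outer(seq_along(in1), seq_along(out1), function(a, b) {
      (pts[in1[a], 1] - pts[out1[b], 1])^2 + (pts[in1[a], 2] - pts[out1[b], 2])^2
    })
    k <- arrayInd(which.min(D), dim(D))
    a <- in1[k[1]]; b <- out1[k[2]]
    ed <- rbind(ed, data.frame(from = min(a, b), to = max(a, b),
                               len = sqrt(min(D))))
  }
}

mst_edges <- function(ed, n) {
  ig <- igraph::graph_from_data_frame(
    data.frame(from = ed$from, to = ed$to, weight = ed$len),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  mst <- igraph::mst(ig, weights = igraph::E(ig)$weight)
  # identify which input rows survived
  el <- igraph::as_edgelist(mst, names = TRUE)
  key_mst <- paste(pmin(as.integer(el[, 1]), as.integer(el[, 2])),
                   pmax(as.integer(el[, 1]), as.integer(el[, 2])))
  key_in <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  # duplicated keys cannot occur (Gabriel edges are unique pairs)
  key_in %in% key_mst & !duplicated(key_in)
}

# remove longest incident edges at nodes exceeding kmax, preferring
# removals that keep the graph connected
cap_degrees <- function(ed, n, kmax = 4L) {
  repeat {
    deg <- tabulate(c(ed$from, ed$to), nbins = n)
    over <- which(deg > kmax)
    if (!length(over)) return(ed)
    v <- over[which.max(deg[over])]
    inc <- which(ed$from == v | ed$to == v)
    inc <- inc[order(-ed$len[inc])]
    drop <- inc[1]
    for (i in inc) {
      trial <- ed[-i, , drop = FALSE]
      if (igraph::is_connected(edges_igraph(trial, n))) { drop <- i; break }
    }
    ed <- ed[-drop, , drop = FALSE]
  }
}

# mean degree of the graph with degree-2 nodes dissolved into their edges
# (each dissolved node removes one edge; exact unless a component is a
# pure cycle of degree-2 nodes, which the generators never produce)
contracted_mean_degree <- function(ed, n) {
  deg <- tabulate(c(ed$from, ed$to), nbins = n)
  d2 <- sum(deg == 2)
  n2 <- sum(deg != 2)
  if (n2 == 0) return(2)
  2 * (nrow(ed) - d2) / n2
}

# remove non-bridge edges until mean degree <= target; removals prefer
# edges whose endpoints stay bifurcations (degree >= 3 after removal), so
# the thinned network keeps its bifurcation density instead of decaying
# into long degree-2 runs
thin_to_degree <- function(ed, n, target, mdeg = function(e) 2 * nrow(e) / n) {
  repeat {
    if (mdeg(ed) <= target) return(ed)
    ig <- edges_igraph(ed, n)
    bridges <- igraph::bridges(ig)
    candidates <- setdiff(seq_len(nrow(ed)), as.integer(bridges))
    if (!length(candidates)) return(ed)
    deg <- tabulate(c(ed$from, ed$to), nbins = n)
    # penalty: endpoints dropping to degree 2 (or below) by this removal
    pen <- (deg[ed$from[candidates]] <= 3) + (deg[ed$to[candidates]] <= 3)
    best <- candidates[pen == min(pen)]
    pick <- if (length(best) > 1) sample(best, 1) else best
    trial <- ed[-pick, , drop = FALSE]
    # stop just above the target rather than overshooting below it
    if (mdeg(trial) < target) return(ed)
    ed <- trial
  }
}

#' Maximal planar triangulation (stacked / Apollonian construction)
#'
#' Builds a maximal planar graph with `3 n - 6` edges by starting from a
#' triangle and repeatedly inserting a vertex inside a face, joined to the
#' face's three corners.  Coordinates realise the planar embedding (each
#' vertex at the centroid of its host face), so the graph attains the
#' planar edge-count bound and its gamma index equals 1.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param seed seed for the face-insertion order.
#' @return a [vessel_graph()] with `3 * n_nodes - 6` edges.
#' @export
maximal_planar_triangulation <- function(n_nodes, seed = 1) {
  if (n_nodes < 3) stop_invalid("n_nodes must be >= 3")
  withr::with_seed(seed, {
    xy <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
    edges <- rbind(c(1, 2), c(2, 3), c(1, 3))
    faces <- list(c(1, 2, 3))
    for (v in seq(4, length.out = n_nodes - 3)) {
      fi <- sample.int(length(faces), 1)
      f <- faces[[fi]]
      xy <- rbind(xy, colMeans(xy[f, , drop = FALSE]))
      edges <- rbind(edges, cbind(f, v))
      faces[[fi]] <- NULL
      faces <- c(faces, list(c(f[1], f[2], v), c(f[2], f[3], v),
                             c(f[1], f[3], v)))
    }
    len <- sqrt(rowSums((xy[edges[, 1], , drop = FALSE] -
                         xy[edges[, 2], , drop = FALSE])^2))
    vessel_graph(
      nodes = data.frame(id = seq_len(n_nodes), x_mm = xy[, 1], y_mm = xy[, 2]),
      edges = data.frame(from = pmin(edges[, 1], edges[, 2]),
                         to = pmax(edges[, 1], edges[, 2]),
                         chord_length_mm = len))
  })
}
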