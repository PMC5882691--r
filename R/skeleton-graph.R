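#' Convert a skeleton image into a vessel bifurcation graph
#'
#' Treats vessels as links and bifurcation points as nodes: skeleton pixels
#' with three or more 8-neighbours are junction pixels (adjacent junction
#' pixels are clustered into one node at their centroid), pixels with one
#' neighbour become endpoint nodes, and degree-2 pixels belong to edge
#' polylines.  Chord length is the along-path distance (1 per axial step,
#' sqrt(2) per diagonal step) times the pixel size.  Post-processing merges
#' nodes closer than `node_merge_px` (thick-vessel junctions skeletonize
#' into nearby junction clusters), prunes spur edges shorter than
#' `prune_px`, dissolves the degree-2 nodes those steps leave behind,
#' discards self-loops, and collapses parallel paths onto a single
#' adjacency entry (shortest length kept, count in `n_parallel`).  Nodes
#' whose degree still exceeds 4 are split with an extraction warning, so
#' reported bifurcation degrees lie in 1..4.
#'
#' @param skel a skeletonized [binary_frame()] (see [skeletonize()]).
#' @param prune_px remove terminal spurs shorter than this many pixels
#'   (default 3).
#' @param node_merge_px merge nodes closer than this many pixels; defaults
#'   to `prune_px` (use the rendered vessel width when known).
#' @return a [vessel_graph()] with coordinates in mm.
#' @export
skeleton_to_graph <- function(skel, prune_px = 3, node_merge_px = prune_px) {
  stopifnot(inherits(skel, "binary_frame"))
  px <- skel$pixels
  mm <- skel$px_size_mm
  nr <- nrow(px); nc <- ncol(px)
  fg <- which(px)
  if (!length(fg)) {
    return(vessel_graph(data.frame(id = integer(0), x_mm = numeric(0),
                                   y_mm = numeric(0)),
                        data.frame(from = integer(0), to = integer(0),
                                   chord_length_mm = numeric(0))))
  }
  pid <- matrix(0L, nr, nc)
  pid[fg] <- seq_along(fg)
  prow <- (fg - 1L) %% nr + 1L
  pcol <- (fg - 1L) %/% nr + 1L

  # 8-neighbour lists per skeleton pixel (indices into fg), with step costs
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  step_cost <- sqrt(offs[, 1]^2 + offs[, 2]^2)
  nbrs <- vector("list", length(fg))
  ncost <- vector("list", length(fg))
  for (k in seq_len(8)) {
    rr <- prow + offs[k, 1]; cc <- pcol + offs[k, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    hit <- integer(length(fg))
    hit[ok] <- pid[cbind(rr[ok], cc[ok])]
    has <- which(hit > 0L)
    for (i in has) {
      nbrs[[i]] <- c(nbrs[[i]], hit[i])
      ncost[[i]] <- c(ncost[[i]], step_cost[k])
    }
  }
  ndeg <- lengths(nbrs)

  is_junction <- ndeg >= 3
  is_node_px <- is_junction | ndeg == 1 | ndeg == 0

  # ensure every connected component owns at least one node pixel
  # (pure cycles have only degree-2 pixels)
  comp_lab <- cpp_label8(px)
  comp_of <- comp_lab[fg]
  for (cmp in setdiff(unique(comp_of), unique(comp_of[is_node_px]))) {
    is_node_px[which(comp_of == cmp)[1]] <- TRUE
  }

  # cluster adjacent junction pixels into single nodes
  jmask <- matrix(FALSE, nr, nc)
  jmask[fg[is_junction]] <- TRUE
  jlab <- cpp_label8(jmask)
  node_of_px <- integer(length(fg))          # node id per node pixel
  jl <- jlab[fg]
  node_of_px[is_junction] <- jl[is_junction]
  n_jnodes <- max(0L, max(jl))
  solo <- which(is_node_px & !is_junction)
  node_of_px[solo] <- n_jnodes + seq_along(solo)
  n_nodes <- n_jnodes + length(solo)

  # node centroids (0-based pixel coords)
  nx <- tapply((pcol - 1)[is_node_px], node_of_px[is_node_px], mean)
  ny <- tapply((prow - 1)[is_node_px], node_of_px[is_node_px], mean)
  ids <- as.integer(names(nx))
  coords <- data.frame(id = ids, x = as.numeric(nx), y = as.numeric(ny))
  coords <- coords[order(coords$id), ]

  # trace edges: from every node pixel, follow each non-node neighbour
  # chain until the next node pixel; direct node-node adjacencies too
  edge_from <- integer(0); edge_to <- integer(0); edge_len <- numeric(0)
  edge_key <- character(0)
  add_edge <- function(a, b, len, key) {
    edge_from <<- c(edge_from, a); edge_to <<- c(edge_to, b)
    edge_len <<- c(edge_len, len); edge_key <<- c(edge_key, key)
  }
  visited <- logical(length(fg))  # path pixels already traced

  for (p in which(is_node_px)) {
    nb <- nbrs[[p]]; cst <- ncost[[p]]
    for (q_i in seq_along(nb)) {
      q <- nb[q_i]
      if (is_node_px[q]) {
        if (node_of_px[q] != node_of_px[p]) {
          key <- paste0("d", min(p, q), "_", max(p, q))
          add_edge(node_of_px[p], node_of_px[q], cst[q_i], key)
        }
        next
      }
      if (visited[q]) next
      # walk the degree-2 chain
      len <- cst[q_i]
      prev <- p; cur <- q
      path_min <- cur
      repeat {
        visited[cur] <- TRUE
        path_min <- min(path_min, cur)
        nxt_i <- which(nbrs[[cur]] != prev)
        # prefer continuing to a node pixel if multiple options (can occur
        # next to junction clusters on slightly thick skeletons)
        cand <- nbrs[[cur]][nxt_i]
        ccst <- ncost[[cur]][nxt_i]
        if (!length(cand)) { cur <- NA_integer_; break }  # dead end
        pick <- if (any(is_node_px[cand])) which(is_node_px[cand])[1] else 1L
        len <- len + ccst[pick]
        prev <- cur; cur <- cand[pick]
        if (is_node_px[cur]) break
        if (visited[cur]) { cur <- NA_integer_; break }   # closed loop
      }
      if (is.na(cur)) next
      add_edge(node_of_px[p], node_of_px[cur], len,
               paste0("p", path_min))
    }
  }

  # deduplicate (each path traced from both ends), drop self-loops
  keep <- !duplicated(edge_key) & edge_from != edge_to
  ed <- data.frame(from = edge_from[keep], to = edge_to[keep],
                   len_px = edge_len[keep])

  g <- build_vessel_graph_px(coords, ed, mm)
  g <- merge_close_nodes(g, node_merge_px * mm)
  iso0 <- g$nodes$id[degree_table(g) == 0]  # genuinely isolated components
  g <- prune_spurs(g, prune_px * mm, protect = iso0)
  g <- dissolve_degree2(g)
  g <- split_high_degree(g, kmax = 4L, min_len_mm = mm)
  g
}

# assemble a vessel_graph from pixel-space pieces, collapsing parallels
build_vessel_graph_px <- function(coords, ed, mm) {
  nodes <- data.frame(id = coords$id, x_mm = coords$x * mm, y_mm = coords$y * mm)
  if (nrow(ed)) {
    a <- pmin(ed$from, ed$to); b <- pmax(ed$from, ed$to)
    key <- paste(a, b)
    o <- order(key, ed$len_px)
    a <- a[o]; b <- b[o]; len <- ed$len_px[o]; key <- key[o]
    first <- !duplicated(key)
    npar <- as.integer(table(key)[key[first]])
    edges <- data.frame(from = a[first], to = b[first],
                        chord_length_mm = len[first] * mm,
                        n_parallel = npar)
  } else {
    edges <- data.frame(from = integer(0), to = integer(0),
                        chord_length_mm = numeric(0), n_parallel = integer(0))
  }
  vessel_graph(nodes, edges)
}

# merge nodes closer than eps_mm (single-linkage via graph components)
merge_close_nodes <- function(g, eps_mm) {
  n <- nrow(g$nodes)
  if (n < 2 || eps_mm <= 0) return(g)
  D <- as.matrix(stats::dist(g$nodes[, c("x_mm", "y_mm")]))
  close <- which(upper.tri(D) & D < eps_mm, arr.ind = TRUE)
  if (!nrow(close)) return(g)
  ig <- igraph::graph_from_edgelist(close, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
  grp <- igraph::components(ig)$membership
  nodes <- data.frame(
    id = sort(unique(grp)),
    x_mm = as.numeric(tapply(g$nodes$x_mm, grp, mean)),
    y_mm = as.numeric(tapply(g$nodes$y_mm, grp, mean)))
  ed <- g$edges
  if (nrow(ed)) {
    ed$from <- grp[match(ed$from, g$nodes$id)]
    ed$to <- grp[match(ed$to, g$nodes$id)]
    ed <- ed[ed$from != ed$to, , drop = FALSE]
  }
  if (nrow(ed)) {
    a <- pmin(ed$from, ed$to); b <- pmax(ed$from, ed$to)
    o <- order(paste(a, b), ed$chord_length_mm)
    a <- a[o]; b <- b[o]
    len <- ed$chord_length_mm[o]; np <- ed$n_parallel[o]
    key <- paste(a, b)
    first <- !duplicated(key)
    npar <- as.integer(tapply(np, key, sum)[key[first]])
    ed <- data.frame(from = a[first], to = b[first],
                     chord_length_mm = len[first], n_parallel = npar)
  }
  vessel_graph(nodes, ed)
}

# drop terminal edges shorter than min_len_mm, then their orphan nodes
# (nodes in `protect` were isolated to begin with and are kept)
prune_spurs <- function(g, min_len_mm, protect = integer(0)) {
  repeat {
    deg <- degree_table(g)
    if (!nrow(g$edges)) return(g)
    spur <- (deg[as.character(g$edges$from)] == 1 |
             deg[as.character(g$edges$to)] == 1) &
            g$edges$chord_length_mm < min_len_mm
    if (!any(spur)) return(drop_isolated_created(g, protect))
    g$edges <- g$edges[!spur, , drop = FALSE]
    g <- drop_isolated_created(g, protect)
  }
}

degree_table <- function(g) {
  d <- setNames(integer(nrow(g$nodes)), g$nodes$id)
  if (nrow(g$edges)) {
    t1 <- table(c(g$edges$from, g$edges$to))
    d[names(t1)] <- as.integer(t1)
  }
  d
}

# remove nodes that lost all edges to pruning but keep genuinely isolated
# single-pixel components (they carry cluster counts)
drop_isolated_created <- function(g, protect = integer(0)) {
  deg <- degree_table(g)
  if (!nrow(g$edges)) return(g)
  keep <- deg > 0 | g$nodes$id %in% protect
  g$nodes <- g$nodes[keep[as.character(g$nodes$id)], , drop = FALSE]
  g
}

# contract chains through degree-2 nodes left by merging/pruning
dissolve_degree2 <- function(g) {
  repeat {
    deg <- degree_table(g)
    cand <- as.integer(names(deg)[deg == 2])
    done <- TRUE
    for (v in cand) {
      inc <- which(g$edges$from == v | g$edges$to == v)
      if (length(inc) != 2) next
      e1 <- g$edges[inc[1], ]; e2 <- g$edges[inc[2], ]
      a <- if (e1$from == v) e1$to else e1$from
      b <- if (e2$from == v) e2$to else e2$from
      if (a == b || a == v || b == v) next  # would create loop/parallel mess
      # refuse if a-b edge already exists (keep it simple, leave the node)
      key <- paste(pmin(g$edges$from, g$edges$to),
                   pmax(g$edges$from, g$edges$to))
      if (paste(min(a, b), max(a, b)) %in% key) next
      g$edges <- g$edges[-inc, , drop = FALSE]
      g$edges <- rbind(g$edges, data.frame(
        from = min(a, b), to = max(a, b),
        chord_length_mm = e1$chord_length_mm + e2$chord_length_mm,
        n_parallel = 1L))
      g$nodes <- g$nodes[g$nodes$id != v, , drop = FALSE]
      done <- FALSE
      break
    }
    if (done) return(g)
  }
}

# split nodes of degree > kmax into two nearby nodes joined by a short edge
split_high_degree <- function(g, kmax = 4L, min_len_mm = 1e-3) {
  repeat {
    deg <- degree_table(g)
    over <- as.integer(names(deg)[deg > kmax])
    if (!length(over)) return(g)
    v <- over[1]
    warning(sprintf("extraction warning: node %d has degree %d; splitting",
                    v, deg[as.character(v)]), call. = FALSE)
    inc <- which(g$edges$from == v | g$edges$to == v)
    other <- ifelse(g$edges$from[inc] == v, g$edges$to[inc], g$edges$from[inc])
    vi <- match(v, g$nodes$id)
    ang <- atan2(g$nodes$y_mm[match(other, g$nodes$id)] - g$nodes$y_mm[vi],
                 g$nodes$x_mm[match(other, g$nodes$id)] - g$nodes$x_mm[vi])
    o <- order(ang)
    take <- inc[o][seq_len(ceiling(length(inc) / 2))]
    new_id <- max(g$nodes$id) + 1L
    g$nodes <- rbind(g$nodes, data.frame(
      id = new_id, x_mm = g$nodes$x_mm[vi] + min_len_mm / 2,
      y_mm = g$nodes$y_mm[vi]))
    sel_from <- g$edges$from[take] == v
    g$edges$from[take][sel_from] <- new_id
    g$edges$to[take][!sel_from] <- new_id
    g$edges <- rbind(g$edges, data.frame(
      from = v, to = new_id, chord_length_mm = min_len_mm, n_parallel = 1L))
  }
}

#' Contract degree-2 nodes into their edges
#'
#' Reduces a graph to bifurcation/endpoint form: every degree-2 node is
#' dissolved and its two edges fused into one with summed chord length.
#' This is the canonical form a skeleton-graph extractor recovers (degree-2
#' skeleton points belong to edge polylines, not to the node set), so use
#' it to put synthetic ground-truth graphs on the same footing as
#' extracted ones before comparing.
#'
#' @param graph a [vessel_graph()].
#' @return a [vessel_graph()] without degree-2 nodes (except where
#'   dissolving one would create a parallel edge or self-loop).
#' @export
contract_degree2 <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  dissolve_degree2(graph)
}

#' Mean chord length of a vessel graph
#'
#' Arithmetic mean of the edge chord lengths, i.e. the typical distance
#' between consecutive vessel bifurcations.
#'
#' @param graph a [vessel_graph()] with at least one edge.
#' @return mean chord length in mm.
#' @export
mean_chord_length <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (!nrow(graph$edges)) stop_undefined("edgeless graph: chord length undefined")
  mean(graph$edges$chord_length_mm)
}
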