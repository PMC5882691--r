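#' Vessel bifurcation graph
#'
#' The network abstraction of a vascular pattern: bifurcation points and
#' vessel endpoints are nodes (with physical coordinates in mm), vessel
#' segments between them are edges carrying their chord length, i.e. the
#' along-vessel distance between consecutive bifurcations.  The adjacency
#' view A_ij (symmetric, zero diagonal) is derived from the edge list; node
#' degree is the row sum of A.
#'
#' @param nodes data.frame with columns `id` (integer), `x_mm`, `y_mm`.
#' @param edges data.frame with columns `from`, `to` (node ids) and
#'   `chord_length_mm`; optionally `n_parallel` (number of distinct
#'   skeleton paths collapsed onto this adjacency entry).
#' @return an object of class `vessel_graph`.
#' @export
vessel_graph <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), all(c("id", "x_mm", "y_mm") %in% names(nodes)))
  if (nrow(edges) == 0) {
    edges <- data.frame(from = integer(0), to = integer(0),
                        chord_length_mm = numeric(0), n_parallel = integer(0))
  }
  stopifnot(all(c("from", "to", "chord_length_mm") %in% names(edges)))
  if (!"n_parallel" %in% names(edges)) edges$n_parallel <- 1L
  if (anyDuplicated(nodes$id)) stop_invalid("duplicate node ids")
  if (nrow(edges)) {
    if (!all(c(edges$from, edges$to) %in% nodes$id)) {
      stop_invalid("edge endpoints must be node ids")
    }
    if (any(edges$from == edges$to)) stop_invalid("self-loops are not allowed")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop_invalid("parallel edges must be collapsed")
  }
  structure(list(nodes = nodes, edges = edges), class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d edges", nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(sprintf(", mean chord %.3f mm", mean(x$edges$chord_length_mm)))
  }
  cat("\n")
  invisible(x)
}

#' Coerce a vessel graph to igraph
#'
#' Isolated nodes are preserved.  Edge chord lengths travel as the
#' `chord_length_mm` edge attribute; coordinates as `x_mm`/`y_mm`.
#'
#' @param g a [vessel_graph()] (an igraph object passes through unchanged).
#' @return an undirected igraph graph.
#' @export
as_igraph <- function(g) {
  if (inherits(g, "igraph")) return(g)
  stopifnot(inherits(g, "vessel_graph"))
  v <- data.frame(name = as.character(g$nodes$id),
                  x_mm = g$nodes$x_mm, y_mm = g$nodes$y_mm)
  e <- g$edges
  if (nrow(e)) {
    e <- data.frame(from = as.character(e$from), to = as.character(e$to),
                    chord_length_mm = e$chord_length_mm)
  } else {
    e <- data.frame(from = character(0), to = character(0),
                    chord_length_mm = numeric(0))
  }
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

#' Adjacency matrix view A_ij of a vessel graph
#'
#' @param g a [vessel_graph()].
#' @return symmetric 0/1 matrix with zero diagonal, rows/cols in node order.
#' @export
adjacency_view <- function(g) {
  stopifnot(inherits(g, "vessel_graph"))
  n <- nrow(g$nodes)
  A <- matrix(0L, n, n, dimnames = list(g$nodes$id, g$nodes$id))
  if (nrow(g$edges)) {
    i <- match(g$edges$from, g$nodes$id)
    j <- match(g$edges$to, g$nodes$id)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  A
}

#' Node degrees of a graph
#'
#' @param g a [vessel_graph()] or igraph object.
#' @return integer vector of degrees (row sums of the adjacency view).
#' @export
node_degrees <- function(g) {
  ig <- as_igraph(g)
  as.integer(igraph::degree(ig))
}

#' Write / read a vessel graph
#'
#' Graphs are exchanged as GraphML (full attributes) plus a plain CSV edge
#' list with columns `source`, `target`, `chord_length_mm`.
#'
#' @param g a [vessel_graph()].
#' @param graphml_path,csv_path output paths; either may be `NULL` to skip.
#' @return invisibly, the paths written.
#' @export
write_vessel_graph <- function(g, graphml_path = NULL, csv_path = NULL) {
  stopifnot(inherits(g, "vessel_graph"))
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(g), graphml_path, format = "graphml")
  }
  if (!is.null(csv_path)) {
    write.csv(data.frame(source = g$edges$from, target = g$edges$to,
                         chord_length_mm = g$edges$chord_length_mm),
              csv_path, row.names = FALSE)
  }
  invisible(c(graphml = graphml_path, csv = csv_path))
}

#' @rdname write_vessel_graph
#' @param path a GraphML file written by [write_vessel_graph()].
#' @export
read_vessel_graph <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(ig)
  nodes <- data.frame(id = seq_len(igraph::vcount(ig)),
                      x_mm = va$x_mm, y_mm = va$y_mm)
  el <- igraph::as_edgelist(ig, names = FALSE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      chord_length_mm = igraph::edge_attr(ig, "chord_length_mm"))
  vessel_graph(nodes, edges)
}
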