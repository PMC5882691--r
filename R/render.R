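#' Rasterize a vessel graph into a binary frame
#'
#' Draws every edge as a straight segment of thickness `vessel_width_px`
#' and every node as a filled disc of the same width, producing the binary
#' image a forming vascular network would present after thresholding.
#' Deterministic for fixed inputs.  Coordinates follow the pixel
#' convention x = column, y = row, 0-based, times `px_size_mm`.
#'
#' @param graph a [vessel_graph()] with all node coordinates inside the
#'   region.
#' @param region_size_px integer pair, output image size.
#' @param px_size_mm mm per pixel.
#' @param vessel_width_px stroke thickness in pixels (>= 1).
#' @param t_h timestamp attached to the frame.
#' @return a [binary_frame()].
#' @export
render_graph <- function(graph, region_size_px = c(400, 400),
                         px_size_mm = 0.0064, vessel_width_px = 3, t_h = 0) {
  ru <- render_reveal(graph, region_size_px, px_size_mm, vessel_width_px)
  px <- matrix(FALSE, region_size_px[1], region_size_px[2])
  px[ru$idx] <- TRUE
  binary_frame(px, px_size_mm = px_size_mm, t_h = t_h)
}

# Shared rasterizer: returns foreground pixel indices plus a reveal score
# u in [0, 1] per pixel encoding the growth order used by
# simulate_vasculogenesis_series: node discs appear first (u in [0, 0.3]),
# then each vessel sprouts from one end (edge_flip picks which) and
# completes at a staggered time (edge_jitter), so cluster merges spread
# over the growth phase as in a percolation process.
render_reveal <- function(graph, region_size_px, px_size_mm, vessel_width_px,
                          node_order = NULL, edge_jitter = NULL,
                          edge_flip = NULL) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (vessel_width_px < 1) stop_invalid("vessel_width_px must be >= 1")
  region_size_px <- as.integer(rep(region_size_px, length.out = 2))
  nr <- region_size_px[1]; nc <- region_size_px[2]
  nodes <- graph$nodes
  edges <- graph$edges
  if (nrow(nodes) == 0) {
    return(list(idx = integer(0), u = numeric(0), nr = nr, nc = nc))
  }
  col0 <- nodes$x_mm / px_size_mm
  row0 <- nodes$y_mm / px_size_mm
  if (any(col0 < 0 | col0 >= nc | row0 < 0 | row0 >= nr)) {
    stop_invalid("node coordinates fall outside the region")
  }
  if (is.null(node_order)) node_order <- seq_len(nrow(nodes))
  if (is.null(edge_jitter)) edge_jitter <- rep(0.5, max(1, nrow(edges)))
  if (is.null(edge_flip)) edge_flip <- rep(FALSE, max(1, nrow(edges)))

  rad <- vessel_width_px / 2
  dd <- seq(-ceiling(rad), ceiling(rad))
  disc <- expand.grid(dr = dd, dc = dd)
  disc <- disc[disc$dr^2 + disc$dc^2 <= rad^2 + 1e-9, ]
  n_off <- nrow(disc)

  stamp <- function(rows, cols, u) {
    # stamp the disc at each (row, col) sample point; returns idx + u
    # (centers clamp to the last pixel so border nodes are not lost)
    r <- rep(pmin(round(rows), nr - 1), each = n_off) + disc$dr
    c <- rep(pmin(round(cols), nc - 1), each = n_off) + disc$dc
    uu <- rep(u, each = n_off)
    ok <- r >= 0 & r < nr & c >= 0 & c < nc
    list(idx = r[ok] + 1L + (c[ok]) * nr, u = uu[ok])
  }

  parts <- list()
  # node discs appear during u in [0, 0.3], in node_order
  u_node <- 0.3 * (order(node_order) - 1) / max(1, nrow(nodes) - 1)
  parts[[1]] <- stamp(row0, col0, u_node)

  if (nrow(edges)) {
    i <- match(edges$from, nodes$id)
    j <- match(edges$to, nodes$id)
    seg_len <- sqrt((row0[i] - row0[j])^2 + (col0[i] - col0[j])^2)
    for (e in seq_len(nrow(edges))) {
      ns <- max(2L, ceiling(seg_len[e] / 0.5) + 1L)
      s <- seq(0, 1, length.out = ns)
      rows <- row0[i[e]] + s * (row0[j[e]] - row0[i[e]])
      cols <- col0[i[e]] + s * (col0[j[e]] - col0[i[e]])
      m <- if (edge_flip[e]) 1 - s else s   # grow from one chosen end
      # per-edge completion time staggered across [0.55, 0.98]
      u <- 0.3 + (0.25 + 0.43 * edge_jitter[e]) * m
      parts[[e + 1L]] <- stamp(rows, cols, u)
    }
  }
  idx <- unlist(lapply(parts, `[[`, "idx"))
  u <- unlist(lapply(parts, `[[`, "u"))
  # a pixel covered by several stamps reveals at the earliest of its scores
  o <- order(u)
  idx <- idx[o]; u <- u[o]
  first <- !duplicated(idx)
  list(idx = idx[first], u = u[first], nr = nr, nc = nc)
}
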