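#' Label connected endothelial-cell clusters in a binary frame
#'
#' Connected components of the foreground are labelled under 8-connectivity
#' (diagonally touching pixels join) and clusters smaller than
#' `min_area_mm2` are excluded from all downstream statistics, mirroring
#' particle-analysis practice of discarding sub-resolution specks.
#'
#' @param frame a [binary_frame()].
#' @param min_area_mm2 minimum retained cluster area in mm^2
#'   (default 1.2e-4).
#' @param connectivity 8 (default) or 4.
#' @return an object of class `cluster_set`: list with `labels` (integer
#'   matrix, 0 = background, retained clusters relabelled 1..n),
#'   `areas_mm2` (per retained label), `n_clusters`, `excluded_count`,
#'   and `px_size_mm`.
#' @export
label_clusters <- function(frame, min_area_mm2 = 1.2e-4, connectivity = 8) {
  stopifnot(inherits(frame, "binary_frame"))
  if (!connectivity %in% c(4, 8)) stop_invalid("connectivity must be 4 or 8")
  if (connectivity == 8) {
    lab <- cpp_label8(frame$pixels)
  } else {
    lab <- matrix(as.integer(EBImage::bwlabel(frame$pixels * 1L)),
                  nrow = nrow(frame$pixels))
  }
  px_area <- frame$px_size_mm^2
  n_raw <- max(lab)
  if (n_raw == 0) {
    return(structure(list(labels = lab, areas_mm2 = numeric(0),
                          n_clusters = 0L, excluded_count = 0L,
                          px_size_mm = frame$px_size_mm),
                     class = "cluster_set"))
  }
  counts <- tabulate(lab[lab > 0], nbins = n_raw)
  areas <- counts * px_area
  keep <- which(areas >= min_area_mm2)
  # relabel retained clusters 1..n, drop the rest
  remap <- integer(n_raw)
  remap[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  structure(list(labels = out, areas_mm2 = areas[keep],
                 n_clusters = length(keep),
                 excluded_count = n_raw - length(keep),
                 px_size_mm = frame$px_size_mm),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters retained (%d excluded by area filter)\n",
              x$n_clusters, x$excluded_count))
  invisible(x)
}

#' Per-frame cluster statistics
#'
#' Computes the vessel density rho (retained foreground area / total image
#' area), the largest-cluster density rho_lc (area of the largest retained
#' connected cluster / total area) used as the percolation order parameter,
#' the cluster count, the largest cluster area, and a logarithmically
#' binned cluster-area histogram.
#'
#' @param cs a [label_clusters()] result.
#' @param frame the [binary_frame()] the clusters were derived from.
#' @return an object of class `frame_stats`: list with `rho`, `rho_lc`,
#'   `n_clusters`, `largest_area_mm2`, `area_hist` (data.frame with bin
#'   edges and counts) and `t_h`.
#' @export
frame_stats <- function(cs, frame) {
  stopifnot(inherits(cs, "cluster_set"), inherits(frame, "binary_frame"))
  total_mm2 <- length(frame$pixels) * frame$px_size_mm^2
  areas <- cs$areas_mm2
  rho <- sum(areas) / total_mm2
  largest <- if (length(areas)) max(areas) else 0
  rho_lc <- largest / total_mm2
  if (length(areas)) {
    # log2-spaced bins anchored at the smallest retained area
    lo <- floor(log2(min(areas)))
    hi <- ceiling(log2(max(areas)) + 1e-12)
    if (hi <= lo) hi <- lo + 1
    breaks <- 2^seq(lo, hi)
    cnt <- as.vector(table(cut(areas, breaks, include.lowest = TRUE)))
    area_hist <- data.frame(bin_lo_mm2 = head(breaks, -1),
                            bin_hi_mm2 = breaks[-1], count = cnt)
  } else {
    area_hist <- data.frame(bin_lo_mm2 = numeric(0), bin_hi_mm2 = numeric(0),
                            count = integer(0))
  }
  structure(list(rho = rho, rho_lc = rho_lc, n_clusters = cs$n_clusters,
                 largest_area_mm2 = largest, area_hist = area_hist,
                 t_h = frame$t_h),
            class = "frame_stats")
}

#' @export
print.frame_stats <- function(x, ...) {
  cat(sprintf("<frame_stats> t = %.3g h: rho = %.4f, rho_lc = %.4f, %d clusters\n",
              x$t_h, x$rho, x$rho_lc, x$n_clusters))
  invisible(x)
}
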