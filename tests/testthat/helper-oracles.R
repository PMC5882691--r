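# Brute-force graph oracles, independent of the package implementation:
# everything works on a plain 0/1 adjacency matrix.

vg_from_edges <- function(n, edges) {
  # edges: 2-column matrix of node pairs; nodes on a line for coordinates
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  ed <- if (nrow(edges)) {
    data.frame(from = pmin(edges[, 1], edges[, 2]),
               to = pmax(edges[, 1], edges[, 2]),
               chord_length_mm = 1)
  } else {
    data.frame(from = integer(0), to = integer(0), chord_length_mm = numeric(0))
  }
  vessel_graph(data.frame(id = seq_len(n), x_mm = seq_len(n), y_mm = 0), ed)
}

vg_path <- function(n) vg_from_edges(n, cbind(1:(n - 1), 2:n))
vg_cycle <- function(n) vg_from_edges(n, rbind(cbind(1:(n - 1), 2:n), c(n, 1)))
vg_star <- function(n) vg_from_edges(n, cbind(1, 2:n))
vg_triangle <- function() vg_from_edges(3, rbind(c(1, 2), c(2, 3), c(1, 3)))

adj_of <- function(g) {
  n <- nrow(g$nodes)
  A <- matrix(0, n, n)
  if (nrow(g$edges)) {
    i <- match(g$edges$from, g$nodes$id); j <- match(g$edges$to, g$nodes$id)
    A[cbind(i, j)] <- 1; A[cbind(j, i)] <- 1
  }
  A
}

random_vg <- function(n, p, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  vg_from_edges(n, pairs[keep, , drop = FALSE])
}

# Floyd-Warshall all-pairs shortest paths
bf_dist <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

bf_components <- function(A) {
  n <- nrow(A)
  D <- bf_dist(A)
  comp <- integer(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cur <- cur + 1
      comp[is.finite(D[i, ])] <- cur
    }
  }
  comp
}

bf_avg_path_lc <- function(A) {
  comp <- bf_components(A)
  sizes <- tabulate(comp)
  lc <- which(comp == which.max(sizes))
  if (length(lc) < 2) return(NA_real_)
  D <- bf_dist(A)[lc, lc]
  mean(D[row(D) != col(D)])
}

bf_mean_degree <- function(A) mean(rowSums(A))

bf_pk <- function(A) {
  k <- rowSums(A)
  tab <- table(k) / nrow(A)
  setNames(as.numeric(tab), names(tab))
}

bf_gamma <- function(A) sum(A) / 2 / (3 * (nrow(A) - 2))

bf_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    ei <- sum(A[nb, nb]) / 2
    ci[i] <- 2 * ei / (k * (k - 1))
  }
  mean(ci)
}

bf_assortativity <- function(A) {
  k <- rowSums(A)
  el <- which(A > 0, arr.ind = TRUE)  # both directions included
  x <- k[el[, 1]]; y <- k[el[, 2]]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

bf_lcc_fraction <- function(A) {
  comp <- bf_components(A)
  max(tabulate(comp)) / nrow(A)
}

# pendant forest by iterative leaf stripping of the largest component;
# returns phi = (pair-weighted mean pendant path length) / <L>
bf_treeness <- function(A) {
  comp <- bf_components(A)
  lc <- which(comp == which.max(tabulate(comp)))
  if (length(lc) < 2) return(NA_real_)
  Al <- A[lc, lc, drop = FALSE]
  L <- bf_avg_path_lc(Al)
  # strip leaves to find the 2-core; removed edges form the pendant forest
  core <- Al
  repeat {
    leaves <- which(rowSums(core) == 1)
    if (!length(leaves)) break
    core[leaves, ] <- 0
    core[, leaves] <- 0
  }
  P <- Al - core   # pendant edges
  P[P < 0] <- 0
  if (sum(P) == 0) return(0)
  compP <- bf_components(P + diag(0, nrow(P)))
  DP <- bf_dist(P)
  tot_d <- 0; tot_p <- 0
  for (cc in unique(compP)) {
    idx <- which(compP == cc)
    # only nodes incident to a pendant edge belong to the forest
    idx <- idx[rowSums(P[idx, , drop = FALSE]) > 0]
    if (length(idx) < 2) next
    Dsub <- DP[idx, idx]
    tot_d <- tot_d + sum(Dsub[upper.tri(Dsub)])
    tot_p <- tot_p + sum(upper.tri(Dsub))
  }
  if (tot_p == 0) return(0)
  min(1, max(0, (tot_d / tot_p) / L))
}
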