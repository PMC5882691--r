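#!/usr/bin/env Rscript
# Stage 5: fractal dimension of aggregation patterns.
#
# Estimator sanity (filled plane -> 2, line -> 1), then the box-counting
# dimension of diffusion-limited cluster-cluster aggregation patterns
# (4000 particles, 512 x 512 lattice, run to a single aggregate, box sizes
# 2..200 px, three seeds) — the regime the early cell-cluster stage of
# vasculogenesis resembles.

suppressMessages(library(vasculonet))
dir.create("results", showWarnings = FALSE)

full <- binary_frame(matrix(TRUE, 512, 512))
line <- binary_frame({m <- matrix(FALSE, 512, 512); m[256, ] <- TRUE; m})
cat(sprintf("sanity: filled square D_f=%.3f, line D_f=%.3f\n",
            box_counting_dimension(full)$d_f,
            box_counting_dimension(line)$d_f))

rows <- lapply(1:3, function(s) {
  agg <- simulate_dlca(4000, grid_size = 512, seed = s)
  bc <- box_counting_dimension(agg)
  cat(sprintf("DLCA seed %d: D_f=%.3f (R^2=%.4f)\n", s, bc$d_f, bc$r2))
  data.frame(seed = s, d_f = bc$d_f, r2 = bc$r2)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/dlca_fractal.csv", row.names = FALSE)
cat(sprintf("mean DLCA box-counting dimension: %.3f\n", mean(tab$d_f)))
cat("note: at 4000 particles the prescribed 2-200 px box range spans the\n")
cat("1-px arm-thickness and saturation scales, reading ~0.1 below the\n")
cat("asymptotic cluster-cluster aggregation value (~1.45)\n")
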