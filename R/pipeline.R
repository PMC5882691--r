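#' Run the full analysis pipeline over an image time series
#'
#' For every frame: label clusters, compute cluster statistics
#' (vessel density rho, largest-cluster density rho_lc, cluster count,
#' area histogram) and the box-counting fractal dimension; skeletonize,
#' extract the bifurcation graph and compute the network metric suite.
#' Then fit the logistic growth model to rho(t) and rho_lc(t) and detect
#' the percolation onset and saturation times on rho_lc(t).  Failures of a
#' downstream step on an individual frame are recorded as `NA` cells, not
#' crashes.  Output is deterministic for a fixed configuration.
#'
#' @param frames a list of [binary_frame()]s, or a directory containing
#'   numbered `*.png` frames.
#' @param px_size_mm,frame_interval_h calibration used when `frames` is a
#'   directory (ignored for in-memory frames, which carry their own).
#' @param min_area_mm2 cluster area filter (default 1.2e-4).
#' @param prune_px,node_merge_px graph-extraction parameters
#'   (see [skeleton_to_graph()]).
#' @param min_box,max_box box-counting bounds; `max_box` is reduced to the
#'   image size when necessary.
#' @param group_label `"control"` or `"treated"`, echoed into the outputs.
#' @param out_dir optional directory: per-frame stats and metrics CSVs, a
#'   growth-fit JSON and a run manifest are written there.
#' @param seed echoed into the manifest (the analysis itself is
#'   deterministic).
#' @return list of class `vasculonet_run` with `frame_stats` (data.frame),
#'   `metrics` (data.frame), `growth` (fits + transition times),
#'   `final_degrees` (degree sample of the last frame) and `manifest`.
#' @export
run_analysis <- function(frames, px_size_mm = 0.0064, frame_interval_h = 0.288,
                         min_area_mm2 = 1.2e-4, prune_px = 3,
                         node_merge_px = NULL, min_box = 2, max_box = 200,
                         group_label = c("control", "treated"),
                         out_dir = NULL, seed = NA_integer_) {
  group_label <- match.arg(group_label)
  if (is.character(frames)) {
    if (!dir.exists(frames)) stop_invalid("input directory not found: ", frames)
    paths <- sort(list.files(frames, pattern = "\\.png$", full.names = TRUE))
    if (!length(paths)) stop_invalid("no PNG frames in ", frames)
    frames <- lapply(seq_along(paths), function(k) {
      read_frame_png(paths[k], px_size_mm = px_size_mm,
                     t_h = (k - 1) * frame_interval_h)
    })
  }
  stopifnot(length(frames) >= 1, all(vapply(frames, inherits, TRUE, "binary_frame")))
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_invalid("frames have mixed sizes")
  }
  max_box <- min(max_box, min(dims[, 1]))
  if (is.null(node_merge_px)) node_merge_px <- prune_px

  safe <- function(expr) tryCatch(expr, error = function(e) NULL,
                                  warning = function(w) suppressWarnings(expr))
  stats_rows <- list()
  metric_rows <- list()
  final_degrees <- integer(0)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    cs <- label_clusters(fr, min_area_mm2 = min_area_mm2)
    fs <- frame_stats(cs, fr)
    d_f <- safe(box_counting_dimension(fr, min_box = min_box, max_box = max_box)$d_f)
    stats_rows[[k]] <- data.frame(
      frame_index = k, t_h = fr$t_h, rho = fs$rho, n_clusters = fs$n_clusters,
      rho_lc = fs$rho_lc, largest_area_mm2 = fs$largest_area_mm2,
      d_f = if (is.null(d_f)) NA_real_ else d_f)
    mg <- safe({
      g <- skeleton_to_graph(skeletonize(fr), prune_px = prune_px,
                             node_merge_px = node_merge_px)
      list(metrics = network_metrics(g, t_h = fr$t_h), graph = g)
    })
    if (is.null(mg)) {
      metric_rows[[k]] <- cbind(frame_index = k,
                                network_metrics(igraph::make_empty_graph(1, directed = FALSE),
                                                t_h = fr$t_h))
      metric_rows[[k]][, setdiff(names(metric_rows[[k]]),
                                 c("frame_index", "t_h"))] <- NA
    } else {
      metric_rows[[k]] <- cbind(frame_index = k, mg$metrics)
      if (k == length(frames)) final_degrees <- node_degrees(mg$graph)
    }
  }
  frame_tab <- do.call(rbind, stats_rows)
  metric_tab <- do.call(rbind, metric_rows)

  fit_of <- function(v) tryCatch(
    fit_logistic(density_series(frame_tab$t_h, pmin(pmax(v, 0), 1))),
    error = function(e) NULL)
  growth <- list(
    rho_fit = fit_of(frame_tab$rho),
    rho_lc_fit = fit_of(frame_tab$rho_lc),
    transitions = tryCatch(
      detect_transitions(density_series(frame_tab$t_h,
                                        pmin(pmax(frame_tab$rho_lc, 0), 1))),
      error = function(e) NULL))
  manifest <- list(package = "vasculonet",
                   version = as.character(utils::packageVersion("vasculonet")),
                   group_label = group_label, seed = seed,
                   n_frames = length(frames),
                   px_size_mm = frames[[1]]$px_size_mm,
                   min_area_mm2 = min_area_mm2, prune_px = prune_px,
                   node_merge_px = node_merge_px,
                   min_box = min_box, max_box = max_box)
  run <- structure(list(frame_stats = frame_tab, metrics = metric_tab,
                        growth = growth, final_degrees = final_degrees,
                        manifest = manifest),
                   class = "vasculonet_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.vasculonet_run <- function(x, ...) {
  cat(sprintf("<vasculonet_run> %s, %d frames; final rho %.3f, final <k> %.3g\n",
              x$manifest$group_label, nrow(x$frame_stats),
              tail(x$frame_stats$rho, 1), tail(x$metrics$mean_degree, 1)))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$frame_stats, file.path(out_dir, "frame_stats.csv"),
            row.names = FALSE)
  write.csv(run$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  gr <- run$growth
  fit_lst <- function(f) if (is.null(f)) NULL else
    list(rho0 = f$rho0, rho_max = f$rho_max, omega = f$omega, rss = f$rss,
         se = as.list(f$se))
  tr <- gr$transitions
  jsonlite::write_json(list(
    group = run$manifest$group_label,
    rho_fit = fit_lst(gr$rho_fit), rho_lc_fit = fit_lst(gr$rho_lc_fit),
    onset_h = if (is.null(tr)) NA else tr$onset_h,
    saturation_h = if (is.null(tr)) NA else tr$saturation_h,
    plateau_value = if (is.null(tr)) NA else tr$plateau_value),
    file.path(out_dir, "growth_fit.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summarize runs by experimental group
#'
#' Aligns runs on their frame time grids, reports per-timepoint group
#' means and standard deviations for every frame statistic and network
#' metric, and compares the pooled final-frame degree samples of the two
#' groups with a two-sample KS test.  With a single run in a group the sd
#' columns are `NA` and means pass through.
#'
#' @param runs list of [run_analysis()] outputs (>= 1 per group).
#' @return list with `summary` (long data.frame: group, t_h, metric, mean,
#'   sd, n) and `ks_final_degrees` (`NULL` unless both groups present).
#' @export
summarize_groups <- function(runs) {
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "vasculonet_run")))
  groups <- vapply(runs, function(r) r$manifest$group_label, "")
  tabs <- lapply(runs, function(r) {
    m <- merge(r$frame_stats, r$metrics[, setdiff(names(r$metrics), "t_h")],
               by = "frame_index")
    m
  })
  grids <- lapply(tabs, function(m) round(m$t_h, 9))
  if (length(unique(vapply(grids, paste, "", collapse = ","))) > 1) {
    stop_invalid("runs have mismatched time grids")
  }
  metrics <- setdiff(names(tabs[[1]]), c("frame_index", "t_h"))
  out <- list()
  for (gl in unique(groups)) {
    sel <- tabs[groups == gl]
    for (mt in metrics) {
      vals <- vapply(sel, function(m) as.numeric(m[[mt]]),
                     numeric(nrow(tabs[[1]])))
      vals <- matrix(vals, nrow = nrow(tabs[[1]]))
      out[[length(out) + 1]] <- data.frame(
        group = gl, t_h = tabs[[1]]$t_h, metric = mt,
        mean = rowMeans(vals, na.rm = TRUE),
        sd = if (length(sel) > 1) apply(vals, 1, sd, na.rm = TRUE) else NA_real_,
        n = length(sel))
    }
  }
  ks <- NULL
  if (length(unique(groups)) == 2) {
    gl <- unique(groups)
    da <- unlist(lapply(runs[groups == gl[1]], `[[`, "final_degrees"))
    db <- unlist(lapply(runs[groups == gl[2]], `[[`, "final_degrees"))
    if (length(da) && length(db)) ks <- ks_compare_degrees(da, db)
  }
  list(summary = do.call(rbind, out), ks_final_degrees = ks)
}
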