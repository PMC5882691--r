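#' Configuration of the synthetic vasculogenesis simulator
#'
#' Bundles the geometry, calibration and morphology parameters used by
#' [simulate_vasculogenesis_series()].  Defaults emulate the imaging
#' conditions of early-embryo bright-field vasculogenesis assays: 6.4 um
#' pixels and a field of view of about 6.6 mm^2 observed over 15 h.
#'
#' @param region_size_px integer pair, image size in pixels.
#' @param px_size_mm mm per pixel side (default 0.0064).
#' @param n_frames number of frames (>= 2).
#' @param t_span_h observation window in hours (default 15).
#' @param seed integer master seed; all randomness derives from it.
#' @param mode `"control_like"` (tree-like final topology) or
#'   `"avastin_like"` (lattice-like, as under anti-VEGF treatment).
#' @param vessel_width_px rendered vessel thickness in pixels (>= 1).
#' @param n_seeds_clusters number of initial cell clusters, which become
#'   the nodes of the target network.
#' @param chord_scale_mm target mean vessel segment length in mm
#'   (default 0.26, the control-like chord length scale).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(region_size_px = c(400, 400),
                              px_size_mm = 0.0064,
                              n_frames = 52,
                              t_span_h = 15,
                              seed = 1,
                              mode = c("control_like", "avastin_like"),
                              vessel_width_px = 3,
                              n_seeds_clusters = 160,
                              chord_scale_mm = 0.26) {
  mode <- match.arg(mode)
  region_size_px <- as.integer(rep(region_size_px, length.out = 2))
  if (any(region_size_px <= 0)) stop_invalid("region_size_px must be positive")
  if (px_size_mm <= 0) stop_invalid("px_size_mm must be positive")
  if (n_frames < 2) stop_invalid("n_frames must be at least 2")
  if (t_span_h <= 0) stop_invalid("t_span_h must be positive")
  if (vessel_width_px < 1) stop_invalid("vessel_width_px must be >= 1")
  if (n_seeds_clusters < 2) stop_invalid("n_seeds_clusters must be >= 2")
  if (chord_scale_mm <= 0) stop_invalid("chord_scale_mm must be positive")
  structure(list(region_size_px = region_size_px, px_size_mm = px_size_mm,
                 n_frames = as.integer(n_frames), t_span_h = t_span_h,
                 seed = as.integer(seed), mode = mode,
                 vessel_width_px = as.integer(vessel_width_px),
                 n_seeds_clusters = as.integer(n_seeds_clusters),
                 chord_scale_mm = chord_scale_mm),
            class = "simulation_config")
}

#' Read a simulation config from YAML or JSON
#'
#' The file holds fields named as in [simulation_config()]; missing fields
#' take the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_invalid("config must be .yaml, .yml or .json")
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) stop_invalid("unknown config fields: ",
                                    paste(unknown, collapse = ", "))
  do.call(simulation_config, lst)
}
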