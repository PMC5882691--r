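#' Skeletonize a binary frame
#'
#' Topology-preserving Guo-Hall thinning to a 1-pixel-wide, 8-connected
#' medial skeleton.  The number of connected components is preserved, so
#' cluster-level statistics agree before and after thinning.
#'
#' @param frame a [binary_frame()].
#' @return a [binary_frame()] containing the skeleton.
#' @export
skeletonize <- function(frame) {
  stopifnot(inherits(frame, "binary_frame"))
  binary_frame(cpp_thin(frame$pixels), px_size_mm = frame$px_size_mm,
               t_h = frame$t_h)
}
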