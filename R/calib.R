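# Pixel <-> physical scale calibration against the background reference grid.
# The scale factor is the mean pixel side length of a known grid square;
# lengths convert linearly: length_px = length_mm * pitch_px / grid_mm.

#' Mean pixel pitch of the reference grid
#'
#' Each row of `endpoint_pairs` holds the pixel coordinates of the two
#' endpoints of one measured grid side, (x1, y1, x2, y2). The pitch is the
#' mean Euclidean endpoint distance over all pairs (five pairs by default in
#' the annotation protocol; any number >= 1 is accepted).
#'
#' @param endpoint_pairs numeric matrix (n x 4).
#' @return mean pitch in pixels.
#' @export
grid_pixel_pitch <- function(endpoint_pairs) {
  m <- as.matrix(endpoint_pairs)
  if (ncol(m) != 4L || nrow(m) < 1L)
    stop("endpoint_pairs must be an n x 4 matrix with n >= 1")
  d <- sqrt((m[, 3] - m[, 1])^2 + (m[, 4] - m[, 2])^2)
  bad <- which(d == 0)
  if (length(bad))
    stop("coincident endpoints in pair ", bad[1])
  mean(d)
}

#' Convert physical length to pixel length via the grid scale
#'
#' @param length_mm length in millimetres.
#' @param pitch_px pixel side length of one grid square.
#' @param grid_mm physical side length of one grid square (default 10 mm).
#' @return length in pixels.
#' @export
mm_to_px <- function(length_mm, pitch_px, grid_mm = 10) {
  if (any(pitch_px <= 0) || any(grid_mm <= 0))
    stop("pitch_px and grid_mm must be positive")
  length_mm * pitch_px / grid_mm
}

#' Convert pixel length to physical length (inverse of [mm_to_px()])
#'
#' @param length_px length in pixels.
#' @inheritParams mm_to_px
#' @return length in millimetres.
#' @export
px_to_mm <- function(length_px, pitch_px, grid_mm = 10) {
  if (any(pitch_px <= 0) || any(grid_mm <= 0))
    stop("pitch_px and grid_mm must be positive")
  length_px * grid_mm / pitch_px
}
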