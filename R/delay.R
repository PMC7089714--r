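#' Point-detector time of flight
#'
#' Straight-line acoustic travel time between a voxel and an element, the
#' delay used by universal back-projection with ideal point-like detectors.
#'
#' @param voxel,element coordinates in mm (depth, lateral, elevation).
#' @param v_s speed of sound in mm/us (default 1.54, soft tissue).
#' @return delay in microseconds (>= 0, symmetric in its two arguments).
#' @export
point_delay <- function(voxel, element, v_s = 1.54) {
  if (!is.finite(v_s) || v_s <= 0) stop("v_s must be > 0", call. = FALSE)
  sqrt(sum((voxel - element)^2)) / v_s
}

#' Focal-line (virtual point detector) time of flight
#'
#' For an elevation-focused linear array the element's acoustic lens focuses
#' on a line through the foci of all elements, parallel to the lateral axis
#' at depth = `focal_length`.  The dominant propagation path from a source to
#' the element crosses this focal line, so each element's focus acts as a
#' virtual point detector: the total path is the element-to-focus distance
#' (the focal length) plus or minus the full 3D focus-to-voxel distance --
#' plus for voxels beyond the focus, minus for voxels in front of it.
#'
#' With `focal_length = 0` the virtual detector coincides with the element
#' and the model reduces exactly to [point_delay()].
#'
#' @param voxel,element coordinates in mm (depth, lateral, elevation); the
#'   element is taken to lie at depth 0.
#' @param focal_length elevation focal distance in mm (>= 0).
#' @param v_s speed of sound in mm/us.
#' @return delay in microseconds.
#' @export
focal_line_delay <- function(voxel, element, focal_length, v_s = 1.54) {
  if (!is.finite(focal_length) || focal_length < 0)
    stop("focal_length must be >= 0", call. = FALSE)
  if (!is.finite(v_s) || v_s <= 0) stop("v_s must be > 0", call. = FALSE)
  if (focal_length == 0) return(point_delay(voxel, element, v_s))
  focus <- c(element[1] + focal_length, element[2], element[3])
  d <- sqrt(sum((voxel - focus)^2))
  s <- if (voxel[1] >= focus[1]) 1 else -1
  (focal_length + s * d) / v_s
}

# Vectorized delay field for one element position over grid axis vectors
# z, x, y (voxel-centre coordinates, mm).  Returns a (nz, nx, ny) array of
# delays in us.  `elem` is the element coordinate; the sign branch of the
# focal-line model depends only on depth, so it recycles along dim 1.
delay_field <- function(z, x, y, elem, model, focal_length, v_s) {
  if (model == "focal_line" && focal_length > 0) {
    ez <- elem[1] + focal_length
    d2 <- outer(outer((z - ez)^2, (x - elem[2])^2, "+"), (y - elem[3])^2, "+")
    s <- ifelse(z >= ez, 1, -1)
    (focal_length + s * sqrt(d2)) / v_s
  } else {
    d2 <- outer(outer((z - elem[1])^2, (x - elem[2])^2, "+"),
                (y - elem[3])^2, "+")
    sqrt(d2) / v_s
  }
}

#' Delay lookup table for a grid and acquisition geometry
#'
#' Evaluates the chosen delay model for every (voxel, element, scan position)
#' combination, vectorized over voxels.  The table can be restricted to
#' subsets of elements and scan positions; a request whose result would
#' exceed `max_bytes` is refused with guidance, since a full-resolution table
#' for the default acquisition would be enormous (the reconstruction core
#' instead evaluates delays on the fly, in depth slabs).
#'
#' @param grid a [build_grid()] object.
#' @param geometry an [array_geometry()].
#' @param trajectory a [scan_trajectory()].
#' @param model `"point"` or `"focal_line"`.
#' @param v_s speed of sound in mm/us.
#' @param elements,positions integer vectors selecting elements / scan
#'   positions (default: all).
#' @param max_bytes memory budget for the returned table (default 1 GB).
#' @return 5-D array of delays in us, indexed
#'   (depth, lateral, elevation, element, scan position).
#' @export
delay_table <- function(grid, geometry, trajectory,
                        model = c("focal_line", "point"), v_s = 1.54,
                        elements = seq_len(geometry$n_elements),
                        positions = seq_len(trajectory$n_positions),
                        max_bytes = 1e9) {
  model <- match.arg(model)
  elements <- as.integer(elements)
  positions <- as.integer(positions)
  if (any(elements < 1L | elements > geometry$n_elements))
    stop("element selection out of range", call. = FALSE)
  if (any(positions < 1L | positions > trajectory$n_positions))
    stop("scan position selection out of range", call. = FALSE)
  n_vox <- prod(grid$dims)
  need <- 8 * n_vox * length(elements) * length(positions)
  if (need > max_bytes)
    stop(sprintf(paste0(
      "delay table would need %.2f GB (> budget %.2f GB); ",
      "restrict `elements`/`positions`, or let reconstruct() evaluate ",
      "delays lazily in tiles"), need / 1e9, max_bytes / 1e9), call. = FALSE)
  ax <- grid_axes(grid)
  ev <- elevation_positions(trajectory)
  out <- array(0, c(grid$dims, length(elements), length(positions)))
  for (si in seq_along(positions)) {
    for (ei in seq_along(elements)) {
      elem <- c(0, geometry$element_lateral_positions[elements[ei]],
                ev[positions[si]])
      out[, , , ei, si] <- delay_field(ax$depth, ax$lateral, ax$elevation,
                                       elem, model, geometry$focal_length, v_s)
    }
  }
  out
}
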