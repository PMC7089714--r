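#' Linear transducer array geometry
#'
#' Describes a 1D linear transducer array, optionally focused in elevation by
#' an acoustic lens.  The array sits in the plane depth = 0, its elements laid
#' out along the lateral axis and centred on lateral = 0, looking into
#' positive depth.  The coordinate frame used throughout the package is
#' right-handed with axes ordered (depth z, lateral x, elevation y); all
#' distances are millimetres, times microseconds, so speeds are mm/us.
#'
#' @param n_elements number of elements (default 128).
#' @param pitch centre-to-centre element spacing in mm.  The default
#'   `86/128` mm makes a 128-element array span an 8.6 cm aperture.
#' @param center_frequency element centre frequency in MHz (default 2.25).
#' @param focal_length elevation focal distance of the acoustic lens in mm;
#'   `0` means an unfocused (point-detector) element.
#'
#' @return An object of class `pact_geometry` with fields `n_elements`,
#'   `pitch`, `center_frequency`, `focal_length` and the derived
#'   `element_lateral_positions` (mm, symmetric about 0).
#' @examples
#' g <- array_geometry()
#' g$element_lateral_positions[65]   # p/2: just right of array centre
#' @export
array_geometry <- function(n_elements = 128L, pitch = 86 / 128,
                           center_frequency = 2.25, focal_length = 0) {
  n_elements <- as.integer(n_elements)
  if (is.na(n_elements) || n_elements < 1L)
    stop("n_elements must be a positive integer", call. = FALSE)
  if (!is.finite(pitch) || pitch <= 0)
    stop("pitch must be > 0", call. = FALSE)
  if (!is.finite(focal_length) || focal_length < 0)
    stop("focal_length must be >= 0", call. = FALSE)
  if (!is.finite(center_frequency) || center_frequency <= 0)
    stop("center_frequency must be > 0", call. = FALSE)
  x <- (seq_len(n_elements) - 1 - (n_elements - 1) / 2) * pitch
  structure(
    list(n_elements = n_elements, pitch = pitch,
         center_frequency = center_frequency, focal_length = focal_length,
         element_lateral_positions = x),
    class = "pact_geometry")
}

#' @export
print.pact_geometry <- function(x, ...) {
  cat(sprintf(
    "Linear array: %d elements, pitch %.4g mm (aperture %.3g mm), %g MHz, %s\n",
    x$n_elements, x$pitch, (x$n_elements - 1) * x$pitch, x$center_frequency,
    if (x$focal_length > 0)
      sprintf("elevation focus at %g mm", x$focal_length)
    else "unfocused"))
  invisible(x)
}

#' Elevation scan trajectory
#'
#' The array is translated mechanically along the elevation axis; each stop is
#' one "scan line" of the synthetic-aperture acquisition.  Either give
#' `n_positions` directly, or give `span` (the total scanned extent in mm) and
#' the number of lines is `round(span / step_size)`: a 40 mm scan at 0.1 mm
#' steps gives 400 lines.
#'
#' @param step_size scan step in mm (default 0.1).
#' @param n_positions number of scan positions (default 400).
#' @param span total scan extent in mm; overrides `n_positions` when given.
#' @param start_offset elevation coordinate of the first scan line (mm).
#' @return An object of class `pact_trajectory`.
#' @examples
#' scan_trajectory(span = 40, step_size = 0.1)$n_positions  # 400
#' @export
scan_trajectory <- function(step_size = 0.1, n_positions = 400L,
                            span = NULL, start_offset = 0) {
  if (!is.finite(step_size) || step_size <= 0)
    stop("step_size must be > 0", call. = FALSE)
  if (!is.null(span)) {
    if (!is.finite(span) || span <= 0) stop("span must be > 0", call. = FALSE)
    n_positions <- as.integer(floor(span / step_size + 0.5))
  }
  n_positions <- as.integer(n_positions)
  if (is.na(n_positions) || n_positions < 1L)
    stop("n_positions must be a positive integer", call. = FALSE)
  structure(
    list(step_size = step_size, n_positions = n_positions,
         start_offset = start_offset),
    class = "pact_trajectory")
}

#' @export
print.pact_trajectory <- function(x, ...) {
  cat(sprintf("Elevation scan: %d lines at %g mm steps (span %g mm from %g mm)\n",
              x$n_positions, x$step_size,
              x$step_size * (x$n_positions - 1), x$start_offset))
  invisible(x)
}

#' Elevation coordinates of all scan lines
#' @param trajectory a [scan_trajectory()].
#' @return numeric vector of elevation positions in mm.
#' @export
elevation_positions <- function(trajectory) {
  trajectory$start_offset +
    (seq_len(trajectory$n_positions) - 1) * trajectory$step_size
}

# round half away from zero; base round() is banker's rounding
round_half_up <- function(x) floor(x + 0.5)

#' Build a reconstruction voxel grid
#'
#' The grid is defined by its physical extents along (depth, lateral,
#' elevation) and a resolution factor RF in voxels per mm, so the voxel size
#' is exactly `1/rf` mm.  Voxel counts are `round(extent * rf)` per axis
#' (half-away-from-zero), reproducing a 200 x 430 x 200 volume for extents
#' (40, 86, 40) mm at RF 5.  Voxel centres lie at
#' `corner + (index - 0.5) / rf` per axis (1-based indices), so the voxels
#' tile the stated extents symmetrically.
#'
#' @param extent_depth,extent_lateral,extent_elevation physical extents in mm.
#' @param rf resolution factor: voxels per mm (reciprocal of the voxel size).
#' @param corner physical coordinate (mm, length-3: depth, lateral, elevation)
#'   of the grid's lower corner.  Default places depth 0 at the array face,
#'   centres the lateral extent on the array centre, and starts elevation at 0
#'   (the default first scan line).
#' @return An object of class `pact_grid` with fields `extent`, `rf`, `dims`,
#'   `voxel_size`, `corner` and `origin` (coordinate of the first voxel
#'   centre).
#' @examples
#' build_grid(40, 86, 40, rf = 5)$dims   # 200 430 200
#' @export
build_grid <- function(extent_depth, extent_lateral, extent_elevation, rf,
                       corner = c(0, -extent_lateral / 2, 0)) {
  extent <- c(extent_depth, extent_lateral, extent_elevation)
  if (any(!is.finite(extent)) || any(extent <= 0))
    stop("grid extents must all be > 0", call. = FALSE)
  if (!is.finite(rf) || rf <= 0)
    stop("rf must be > 0", call. = FALSE)
  if (length(corner) != 3L || any(!is.finite(corner)))
    stop("corner must be a finite length-3 coordinate", call. = FALSE)
  dims <- as.integer(round_half_up(extent * rf))
  if (any(dims < 1L))
    stop("grid extents are smaller than one voxel at this rf", call. = FALSE)
  structure(
    list(extent = extent, rf = rf, dims = dims, voxel_size = 1 / rf,
         corner = as.numeric(corner),
         origin = as.numeric(corner) + 0.5 / rf),
    class = "pact_grid")
}

#' @export
print.pact_grid <- function(x, ...) {
  cat(sprintf(
    "Recon grid: %d x %d x %d voxels (depth x lateral x elevation), %g mm voxels (RF %g)\n",
    x$dims[1], x$dims[2], x$dims[3], x$voxel_size, x$rf))
  invisible(x)
}

#' Voxel-centre coordinates along each grid axis
#' @param grid a [build_grid()] object.
#' @return list with numeric vectors `depth`, `lateral`, `elevation` (mm).
#' @export
grid_axes <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$corner[k] + (seq_len(grid$dims[k]) - 0.5) / grid$rf)
  names(ax) <- c("depth", "lateral", "elevation")
  ax
}

#' Physical coordinate of a voxel centre
#' @param grid a [build_grid()] object.
#' @param index 1-based integer triple (depth, lateral, elevation).
#' @return coordinate in mm (length-3 numeric).
#' @export
voxel_center <- function(grid, index) {
  index <- as.integer(index)
  if (length(index) != 3L || any(index < 1L) || any(index > grid$dims))
    stop("voxel index out of range", call. = FALSE)
  grid$corner + (index - 0.5) / grid$rf
}

#' Voxel index containing a physical coordinate
#' @param grid a [build_grid()] object.
#' @param coord coordinate in mm (length-3 numeric).
#' @return 1-based integer triple; errors if the point is outside the grid.
#' @export
voxel_index <- function(grid, coord) {
  idx <- as.integer(round((coord - grid$corner) * grid$rf + 0.5))
  if (any(idx < 1L) || any(idx > grid$dims))
    stop("coordinate outside the grid", call. = FALSE)
  idx
}

#' Physical position of one element at one scan line
#'
#' Elements live at depth 0; the lateral coordinate comes from the array
#' layout and the elevation coordinate from the scan trajectory.  Indices are
#' 1-based.
#'
#' @param geometry an [array_geometry()].
#' @param trajectory a [scan_trajectory()].
#' @param element_index element number, `1..n_elements`.
#' @param scan_index scan line number, `1..n_positions`.
#' @return coordinate (depth, lateral, elevation) in mm.
#' @export
element_position <- function(geometry, trajectory, element_index, scan_index) {
  element_index <- as.integer(element_index)
  scan_index <- as.integer(scan_index)
  if (is.na(element_index) || element_index < 1L ||
      element_index > geometry$n_elements)
    stop("element_index out of range", call. = FALSE)
  if (is.na(scan_index) || scan_index < 1L ||
      scan_index > trajectory$n_positions)
    stop("scan_index out of range", call. = FALSE)
  c(0,
    geometry$element_lateral_positions[element_index],
    trajectory$start_offset + (scan_index - 1) * trajectory$step_size)
}

#' Read an acquisition/reconstruction config file
#'
#' The config is plain YAML key--value.  Recognized keys: `n_elements`,
#' `pitch_mm`, `center_frequency_mhz`, `focal_length_mm`, `scan_step_mm`,
#' `n_scan_positions`, `scan_start_mm`, `speed_of_sound_mm_per_us`, `rf`,
#' `extent_depth_mm`, `extent_lateral_mm`, `extent_elevation_mm`,
#' `delay_model` (`point` or `focal_line`), `weighting` (`uniform` or
#' `solid_angle`).  Unknown keys produce a warning, not an error.
#'
#' @param path path to the YAML file.
#' @return list with elements `geometry`, `trajectory`, `grid`, `v_s`,
#'   `delay_model`, `weighting`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("n_elements", "pitch_mm", "center_frequency_mhz",
             "focal_length_mm", "scan_step_mm", "n_scan_positions",
             "scan_start_mm", "speed_of_sound_mm_per_us", "rf",
             "extent_depth_mm", "extent_lateral_mm", "extent_elevation_mm",
             "delay_model", "weighting")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "),
            call. = FALSE)
  pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  geometry <- array_geometry(
    n_elements = pick("n_elements", 128L),
    pitch = pick("pitch_mm", 86 / 128),
    center_frequency = pick("center_frequency_mhz", 2.25),
    focal_length = pick("focal_length_mm", 0))
  trajectory <- scan_trajectory(
    step_size = pick("scan_step_mm", 0.1),
    n_positions = pick("n_scan_positions", 400L),
    start_offset = pick("scan_start_mm", 0))
  grid <- build_grid(
    extent_depth = pick("extent_depth_mm", 40),
    extent_lateral = pick("extent_lateral_mm", 86),
    extent_elevation = pick("extent_elevation_mm", 40),
    rf = pick("rf", 5))
  delay_model <- match.arg(pick("delay_model", "focal_line"),
                           c("focal_line", "point"))
  weighting <- match.arg(pick("weighting", "uniform"),
                         c("uniform", "solid_angle"))
  list(geometry = geometry, trajectory = trajectory, grid = grid,
       v_s = pick("speed_of_sound_mm_per_us", 1.54),
       delay_model = delay_model, weighting = weighting)
}
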