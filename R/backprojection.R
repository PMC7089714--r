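#' Reconstructed volume container
#'
#' Holds the back-projected initial pressure on a [build_grid()] lattice,
#' indexed (depth, lateral, elevation), plus the reconstruction settings that
#' produced it.
#'
#' @param values numeric 3-D array matching `grid$dims`.
#' @param grid the [build_grid()] object.
#' @param meta optional list of provenance fields.
#' @return An object of class `pact_volume`.
#' @export
pact_volume <- function(values, grid, meta = list()) {
  if (!is.array(values) || !identical(dim(values), as.integer(grid$dims)))
    stop("values shape must equal grid dims", call. = FALSE)
  structure(list(values = values, grid = grid, meta = meta),
            class = "pact_volume")
}

#' @export
print.pact_volume <- function(x, ...) {
  d <- x$grid$dims
  cat(sprintf("Reconstructed volume: %d x %d x %d voxels (%g mm), range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$grid$voxel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

# shared validation for both reconstruction paths
check_recon_inputs <- function(data, geometry, trajectory, grid) {
  d <- dim(data$samples)
  if (d[2] != geometry$n_elements || d[3] != trajectory$n_positions)
    stop(sprintf(
      "sinogram shape (%d elements x %d positions) does not match geometry (%d x %d)",
      d[2], d[3], geometry$n_elements, trajectory$n_positions), call. = FALSE)
  bad <- which(!is.finite(data$samples))
  if (length(bad)) {
    idx <- arrayInd(bad[1], d)
    stop(sprintf(
      "non-finite sample at (time %d, element %d, position %d)",
      idx[1], idx[2], idx[3]), call. = FALSE)
  }
  if (prod(grid$dims) < 1) stop("empty reconstruction grid", call. = FALSE)
  invisible(TRUE)
}

# integrand traces per the selected conditioning
condition_traces <- function(data, integrand, prefilter_band) {
  if (!is.null(prefilter_band)) data <- bandpass_filter(data, prefilter_band)
  if (integrand == "ubp") ubp_term(data)$samples else data$samples
}

#' Universal back-projection reconstruction (vectorized core)
#'
#' Accumulates, at every voxel, the conditioned integrand of every element
#' trace at every scan position, evaluated at that voxel's time of flight
#' under the chosen delay model:
#' `p0(v) = sum_{e,s} w(v,e,s) b_{e,s}(tau(v,e,s))`.
#' The integrand `b` is `2p - 2t dp/dt` ([ubp_term()], the default) or the
#' raw pressure (`integrand = "das"`, plain delay-and-sum).  The sum is
#' deterministic and linear in the data; accumulation is in double precision.
#'
#' Weighting: `"uniform"` divides each voxel's sum by the number of
#' contributing (element, position) pairs (all pairs, or those passing the
#' optional acceptance-angle mask), absorbing the solid-angle normalization
#' into a count; `"solid_angle"` weights each term by cos(theta)/d^2 -- theta
#' the angle between the voxel-to-element ray and the element normal --
#' renormalized per voxel.
#'
#' The volume is processed in depth slabs sized from `tile_bytes` so memory
#' stays bounded at full acquisition scale; tiling does not change results.
#'
#' @param data a [sensor_data()] sinogram.
#' @param geometry an [array_geometry()].
#' @param trajectory a [scan_trajectory()].
#' @param grid a [build_grid()] object.
#' @param model delay model, `"focal_line"` or `"point"`.
#' @param weighting `"uniform"` or `"solid_angle"`.
#' @param v_s speed of sound in mm/us.
#' @param integrand `"ubp"` (2p - 2t dp/dt) or `"das"` (raw pressure).
#' @param aperture_half_angle optional acceptance half-angle in degrees
#'   measured from the element normal; pairs seeing a voxel outside the cone
#'   are excluded.  `NULL` (default) applies no cut.
#' @param prefilter_band optional length-2 MHz band for a zero-phase
#'   band-pass before conditioning; `NULL` (default) = no filtering.
#' @param tile_bytes memory budget for per-pair scratch arrays (default 1 GB).
#' @param progress optional `function(scan_index, n_positions)` called after
#'   each scan line; reporting does not alter any output value.
#' @return a [pact_volume()].
#' @seealso [reconstruct_reference()] for the naive loop oracle.
#' @export
reconstruct <- function(data, geometry, trajectory, grid,
                        model = c("focal_line", "point"),
                        weighting = c("uniform", "solid_angle"),
                        v_s = 1.54, integrand = c("ubp", "das"),
                        aperture_half_angle = NULL, prefilter_band = NULL,
                        tile_bytes = 1e9, progress = NULL) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  integrand <- match.arg(integrand)
  check_recon_inputs(data, geometry, trajectory, grid)
  b <- condition_traces(data, integrand, prefilter_band)
  fs <- data$sampling_rate
  t0 <- data$t0
  ax <- grid_axes(grid)
  ev <- elevation_positions(trajectory)
  dims <- grid$dims
  nz <- dims[1]; nx <- dims[2]; ny <- dims[3]
  cos_cut <- if (is.null(aperture_half_angle)) NULL
             else cos(aperture_half_angle * pi / 180)
  need_w <- weighting == "solid_angle"
  need_count <- weighting == "uniform" && !is.null(cos_cut)

  # depth-slab size: ~8 scratch arrays of nz_slab * nx * ny doubles per pair
  slab_nz <- max(1L, min(nz, floor(tile_bytes / (8 * 8 * nx * ny))))
  slab_starts <- seq(1L, nz, by = slab_nz)

  acc <- array(0, dims)
  wsum <- if (need_w || need_count) array(0, dims) else NULL
  n_pairs <- geometry$n_elements * trajectory$n_positions

  for (si in seq_len(trajectory$n_positions)) {
    for (ei in seq_len(geometry$n_elements)) {
      elem <- c(0, geometry$element_lateral_positions[ei], ev[si])
      trace <- b[, ei, si]
      for (z0 in slab_starts) {
        z1 <- min(z0 + slab_nz - 1L, nz)
        zi <- z0:z1
        zc <- ax$depth[zi]
        tau <- delay_field(zc, ax$lateral, ax$elevation, elem, model,
                           geometry$focal_length, v_s)
        val <- interp_trace(trace, tau, fs, t0)
        if (!is.null(cos_cut) || need_w) {
          d2 <- outer(outer((zc - elem[1])^2,
                            (ax$lateral - elem[2])^2, "+"),
                      (ax$elevation - elem[3])^2, "+")
          dpt <- sqrt(d2)
          cosang <- (zc - elem[1]) / dpt   # recycles along dim 1
          cosang[dpt == 0] <- 1
          inside <- if (is.null(cos_cut)) TRUE else cosang >= cos_cut
          if (need_w) {
            w <- cosang / d2
            w[d2 == 0] <- 0
            if (!is.null(cos_cut)) w <- w * inside
            acc[zi, , ] <- acc[zi, , , drop = FALSE] + w * val
            wsum[zi, , ] <- wsum[zi, , , drop = FALSE] + w
          } else {
            acc[zi, , ] <- acc[zi, , , drop = FALSE] + val * inside
            wsum[zi, , ] <- wsum[zi, , , drop = FALSE] + inside
          }
        } else {
          acc[zi, , ] <- acc[zi, , , drop = FALSE] + val
        }
      }
    }
    if (!is.null(progress)) progress(si, trajectory$n_positions)
  }

  values <- if (is.null(wsum)) acc / n_pairs
            else ifelse(wsum > 0, acc / wsum, 0)
  values <- array(values, dims)
  pact_volume(values, grid,
              meta = list(model = model, weighting = weighting, v_s = v_s,
                          integrand = integrand,
                          aperture_half_angle = aperture_half_angle))
}

#' Naive triple-loop reference reconstruction (the correctness oracle)
#'
#' Identical contract to [reconstruct()], implemented as the plainest
#' possible nested loops over voxels, elements and scan positions with scalar
#' delay and interpolation calls -- the readable mirror of the per-element,
#' per-scan-line loop structure of back-projection.  It exists to serve as an
#' independent oracle for the vectorized core on small problems; it is far
#' too slow for production grids.
#'
#' @inheritParams reconstruct
#' @return a [pact_volume()].
#' @export
reconstruct_reference <- function(data, geometry, trajectory, grid,
                                  model = c("focal_line", "point"),
                                  weighting = c("uniform", "solid_angle"),
                                  v_s = 1.54, integrand = c("ubp", "das"),
                                  aperture_half_angle = NULL,
                                  prefilter_band = NULL) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  integrand <- match.arg(integrand)
  check_recon_inputs(data, geometry, trajectory, grid)
  b <- condition_traces(data, integrand, prefilter_band)
  fs <- data$sampling_rate
  t0 <- data$t0
  dims <- grid$dims
  cos_cut <- if (is.null(aperture_half_angle)) NULL
             else cos(aperture_half_angle * pi / 180)
  values <- array(0, dims)
  for (iz in seq_len(dims[1])) {
    for (ix in seq_len(dims[2])) {
      for (iy in seq_len(dims[3])) {
        v <- voxel_center(grid, c(iz, ix, iy))
        acc <- 0
        wsum <- 0
        for (si in seq_len(trajectory$n_positions)) {
          for (ei in seq_len(geometry$n_elements)) {
            elem <- element_position(geometry, trajectory, ei, si)
            dpt <- sqrt(sum((v - elem)^2))
            cosang <- if (dpt == 0) 1 else (v[1] - elem[1]) / dpt
            if (!is.null(cos_cut) && cosang < cos_cut) next
            tau <- if (model == "focal_line")
              focal_line_delay(v, elem, geometry$focal_length, v_s)
            else point_delay(v, elem, v_s)
            w <- if (weighting == "solid_angle") {
              if (dpt == 0) 0 else cosang / dpt^2
            } else 1
            acc <- acc + w * sample_at(b[, ei, si], tau, fs, t0)
            wsum <- wsum + w
          }
        }
        values[iz, ix, iy] <- if (wsum > 0) acc / wsum else 0
      }
    }
  }
  pact_volume(values, grid,
              meta = list(model = model, weighting = weighting, v_s = v_s,
                          integrand = integrand, reference = TRUE,
                          aperture_half_angle = aperture_half_angle))
}
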