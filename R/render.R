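#' Depth-encoded maximum intensity projection
#'
#' Projects a reconstructed volume along depth: at each (lateral, elevation)
#' pixel the intensity is the maximum of |p0| over depth (back-projection
#' output is signed, so the magnitude is projected) and the depth map records
#' where that maximum occurs, ties broken toward the shallowest depth.  The
#' rendered RGB image encodes depth as hue through a colormap and intensity
#' as brightness, with the stated upper percentile of the intensity image
#' mapped to full brightness.
#'
#' @param volume a [pact_volume()].
#' @param colormap palette name passed to [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @param clip_percentile intensity percentile mapped to full brightness
#'   (default 99).
#' @return An object of class `pact_mip` with fields `intensity`
#'   (lateral x elevation), `depth_mm` (same shape), `rgb`
#'   (lateral x elevation x 3, in `[0, 1]`) and `grid`.
#' @export
depth_encoded_mip <- function(volume, colormap = "viridis",
                              clip_percentile = 99) {
  if (!inherits(volume, "pact_volume")) stop("need a pact_volume",
                                             call. = FALSE)
  a <- abs(volume$values)
  if (length(a) == 0) stop("empty volume", call. = FALSE)
  d <- dim(a)
  nz <- d[1]
  flat <- matrix(a, nrow = nz)                # columns are (lateral, elev)
  imax <- max.col(t(flat), ties.method = "first")   # shallowest on ties
  intensity <- matrix(flat[cbind(imax, seq_along(imax))], d[2], d[3])
  depths <- grid_axes(volume$grid)$depth
  depth_mm <- matrix(depths[imax], d[2], d[3])

  hi <- stats::quantile(intensity, clip_percentile / 100, names = FALSE)
  bright <- if (hi > 0) pmin(intensity / hi, 1) else intensity * 0
  ncol_pal <- 256L
  pal <- grDevices::hcl.colors(ncol_pal, colormap)
  zrange <- range(depths)
  rel <- if (diff(zrange) > 0) (depth_mm - zrange[1]) / diff(zrange) else
    depth_mm * 0
  ci <- pmin(pmax(as.integer(rel * (ncol_pal - 1)) + 1L, 1L), ncol_pal)
  base <- grDevices::col2rgb(pal) / 255          # 3 x ncol_pal
  rgb <- array(0, c(d[2], d[3], 3))
  for (ch in 1:3)
    rgb[, , ch] <- matrix(base[ch, ci], d[2], d[3]) * bright
  structure(list(intensity = intensity, depth_mm = depth_mm, rgb = rgb,
                 grid = volume$grid, colormap = colormap,
                 clip_percentile = clip_percentile),
            class = "pact_mip")
}

#' @export
print.pact_mip <- function(x, ...) {
  cat(sprintf(
    "Depth-encoded MIP: %d x %d pixels (lateral x elevation), depth range [%.3g, %.3g] mm\n",
    nrow(x$intensity), ncol(x$intensity), min(x$depth_mm), max(x$depth_mm)))
  invisible(x)
}

#' Write a depth-encoded MIP as a PNG image
#'
#' Rows of the image run along elevation (the scan direction), columns along
#' the lateral axis.
#'
#' @param mip a [depth_encoded_mip()] result.
#' @param path output file path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mip_png <- function(mip, path) {
  img <- aperm(mip$rgb, c(2, 1, 3))
  png::writePNG(img, path)
  invisible(path)
}

#' @param x a `pact_mip`.
#' @param ... ignored.
#' @rdname depth_encoded_mip
#' @export
plot.pact_mip <- function(x, ...) {
  img <- aperm(x$rgb, c(2, 1, 3))
  ax <- grid_axes(x$grid)
  graphics::plot(NA, xlim = range(ax$lateral), ylim = range(ax$elevation),
                 xlab = "lateral (mm)", ylab = "elevation (mm)",
                 asp = 1, main = "Depth-encoded MIP")
  graphics::rasterImage(img, min(ax$lateral), min(ax$elevation),
                        max(ax$lateral), max(ax$elevation))
  invisible(x)
}

#' @param x a `pact_volume`.
#' @param ... passed to [depth_encoded_mip()].
#' @rdname depth_encoded_mip
#' @export
plot.pact_volume <- function(x, ...) {
  plot(depth_encoded_mip(x, ...))
}

#' Locate the strongest well-separated peaks of a volume
#'
#' Greedy non-maximum suppression: repeatedly take the global argmax of
#' |p0| and zero out a ball of `min_separation` around it.  Used to recover
#' point-absorber positions from a reconstruction.
#'
#' @param volume a [pact_volume()].
#' @param n number of peaks to return.
#' @param min_separation suppression radius in mm (default 3 voxel sizes).
#' @return numeric matrix (n x 3) of peak voxel-centre coordinates in mm.
#' @export
find_peaks <- function(volume, n, min_separation = 3 * volume$grid$voxel_size) {
  a <- abs(volume$values)
  ax <- grid_axes(volume$grid)
  out <- matrix(NA_real_, n, 3)
  for (j in seq_len(n)) {
    i <- which.max(a)
    idx <- arrayInd(i, dim(a))
    ctr <- c(ax$depth[idx[1]], ax$lateral[idx[2]], ax$elevation[idx[3]])
    out[j, ] <- ctr
    near_z <- abs(ax$depth - ctr[1]) <= min_separation
    near_x <- abs(ax$lateral - ctr[2]) <= min_separation
    near_y <- abs(ax$elevation - ctr[3]) <= min_separation
    a[near_z, near_x, near_y] <- -Inf
  }
  out
}
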