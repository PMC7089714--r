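#' Write a sinogram to disk
#'
#' Native on-disk layout: a raw little-endian binary file of the sample cube
#' in column-major order (time fastest, then element, then scan position)
#' plus a JSON sidecar (same path with extension `.json`) holding
#' `dims`, `dtype`, `byte_order`, `sampling_rate_mhz` and `t0_us`.
#'
#' @param data a [sensor_data()] object.
#' @param path output path for the binary file (conventionally `.raw`).
#' @param dtype on-disk sample type: `"float32"` (compact, default) or
#'   `"float64"` (lossless).
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(data, path, dtype = c("float32", "float64")) {
  dtype <- match.arg(dtype)
  stopifnot(inherits(data, "pact_sensor_data"))
  size <- if (dtype == "float32") 4L else 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(data$samples), con, size = size, endian = "little")
  meta <- list(dims = dim(data$samples), dtype = dtype,
               byte_order = "little",
               sampling_rate_mhz = data$sampling_rate, t0_us = data$t0)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  if (grepl("\\.[A-Za-z0-9]+$", path))
    sub("\\.[A-Za-z0-9]+$", ".json", path)
  else paste0(path, ".json")
}

#' Read a sinogram written by [write_sinogram()]
#'
#' @param path path to the binary file; its JSON sidecar must sit alongside.
#' @return a [sensor_data()] object.
#' @export
read_sinogram <- function(path) {
  if (!file.exists(path))
    stop("sinogram file not found: ", path, call. = FALSE)
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("sinogram sidecar not found: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  need <- c("dims", "dtype", "sampling_rate_mhz", "t0_us")
  if (!all(need %in% names(meta)))
    stop("sinogram sidecar is missing fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  dims <- as.integer(meta$dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("sinogram sidecar dims must be a positive integer triple",
         call. = FALSE)
  size <- if (identical(meta$dtype, "float64")) 8L else 4L
  con <- file(path, "rb")
  on.exit(close(con))
  n <- prod(dims)
  x <- readBin(con, what = "numeric", n = n, size = size, endian = "little")
  if (length(x) != n)
    stop("sinogram file is truncated: expected ", n, " samples, got ",
         length(x), call. = FALSE)
  sensor_data(array(x, dims), as.numeric(meta$sampling_rate_mhz),
              as.numeric(meta$t0_us))
}

#' Write a reconstructed volume to disk
#'
#' Two formats, chosen by extension:
#' * `.nii` -- uncompressed NIfTI-1, voxel size `1/rf` mm in the header;
#'   lossless (values stored as written) and byte-deterministic.
#' * `.tif`/`.tiff` -- multi-page 32-bit float TIFF, one page per elevation
#'   slice, each page (depth x lateral).  TIFF float storage is defined on
#'   `[0, 1]`, so magnitudes are min--max normalized; the affine scale is
#'   recorded in the sidecar.
#'
#' Both formats get a JSON sidecar carrying the grid metadata (extents, rf,
#' corner) so the volume can be re-associated with physical coordinates.
#'
#' @param volume a [pact_volume()].
#' @param path output path ending in `.nii`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pact_volume"))
  g <- volume$grid
  meta <- list(dims = g$dims, rf = g$rf, voxel_size_mm = g$voxel_size,
               extent_mm = g$extent, corner_mm = g$corner,
               axes = c("depth", "lateral", "elevation"))
  if (grepl("\\.nii$", path)) {
    img <- RNifti::asNifti(volume$values)
    RNifti::pixdim(img) <- rep(g$voxel_size, 3)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path)) {
    v <- abs(volume$values)
    lo <- min(v); hi <- max(v)
    scaled <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
    pages <- lapply(seq_len(g$dims[3]), function(iy) scaled[, , iy])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta$value_scale <- list(lo = lo, hi = hi, stored = "abs, min-max scaled")
  } else {
    stop("unsupported volume format: ", path, " (use .nii or .tif)",
         call. = FALSE)
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a `.nii` volume written by [write_volume()]
#'
#' @param path path to the `.nii` file; the JSON grid sidecar is used when
#'   present, otherwise the grid is rebuilt from the NIfTI header (default
#'   corner).
#' @return a [pact_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("volume file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  values <- array(as.numeric(img), dim(img))
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    grid <- build_grid(meta$extent_mm[1], meta$extent_mm[2],
                       meta$extent_mm[3], meta$rf, corner = meta$corner_mm)
  } else {
    vs <- RNifti::pixdim(img)[1]
    d <- dim(values)
    grid <- build_grid(d[1] * vs, d[2] * vs, d[3] * vs, 1 / vs)
  }
  if (!identical(as.integer(dim(values)), grid$dims))
    stop("volume data does not match its grid metadata", call. = FALSE)
  pact_volume(values, grid)
}

#' Read a phantom description file
#'
#' YAML with an `absorbers` list (each entry: `center_mm` length-3,
#' `radius_mm`, `amplitude`) and optional top-level `noise_sd` and `seed`.
#'
#' @param path path to the YAML file.
#' @return a [phantom()].
#' @export
read_phantom <- function(path) {
  if (!file.exists(path))
    stop("phantom file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  abs_list <- cfg$absorbers
  if (is.null(abs_list))
    stop("phantom file must contain an 'absorbers' list", call. = FALSE)
  centers <- do.call(rbind, lapply(abs_list, function(a) {
    if (is.null(a$center_mm) || length(a$center_mm) != 3L)
      stop("each absorber needs a length-3 center_mm", call. = FALSE)
    as.numeric(a$center_mm)
  }))
  radii <- vapply(abs_list, function(a)
    if (is.null(a$radius_mm)) 0 else as.numeric(a$radius_mm), numeric(1))
  amps <- vapply(abs_list, function(a)
    if (is.null(a$amplitude)) 1 else as.numeric(a$amplitude), numeric(1))
  phantom(centers, radii, amps,
          noise_sd = if (is.null(cfg$noise_sd)) 0 else cfg$noise_sd,
          seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}
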