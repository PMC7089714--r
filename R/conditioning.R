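#' Sinogram container
#'
#' Wraps the raw acquisition cube: pressure samples indexed
#' (time sample, element, scan position), with the sampling rate and the time
#' of the first sample relative to the laser pulse.
#'
#' @param samples numeric 3-D array (time x element x scan position); a
#'   matrix (time x element) is promoted to a single scan position.
#' @param sampling_rate sampling rate in MHz.
#' @param t0 time of the first sample in us (default 0).
#' @return An object of class `pact_sensor_data`.
#' @export
sensor_data <- function(samples, sampling_rate, t0 = 0) {
  if (is.matrix(samples)) dim(samples) <- c(dim(samples), 1L)
  if (!is.array(samples) || length(dim(samples)) != 3L)
    stop("samples must be a 3-D array (time x element x position)",
         call. = FALSE)
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0", call. = FALSE)
  if (!is.finite(t0)) stop("t0 must be finite", call. = FALSE)
  structure(list(samples = samples, sampling_rate = sampling_rate, t0 = t0),
            class = "pact_sensor_data")
}

#' @export
print.pact_sensor_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "Sinogram: %d time samples x %d elements x %d scan positions @ %g MHz (t0 = %g us)\n",
    d[1], d[2], d[3], x$sampling_rate, x$t0))
  invisible(x)
}

#' Time axis of a sinogram
#' @param data a [sensor_data()] object.
#' @return sample times in us.
#' @export
time_axis <- function(data) {
  data$t0 + (seq_len(dim(data$samples)[1]) - 1) / data$sampling_rate
}

#' Universal back-projection integrand 2p - 2t dp/dt
#'
#' Converts pressure traces into the back-projection term
#' `b(t) = 2 p(t) - 2 t p'(t)`, with the derivative taken by second-order
#' central finite differences (first-order one-sided at the two ends) and `t`
#' the absolute time of flight `t0 + k / sampling_rate`.  The operator is
#' linear in the input; a constant trace maps to twice itself and a trace
#' linear in `t` is annihilated at interior samples.
#'
#' @param data a [sensor_data()] object, or a numeric vector/matrix/array of
#'   traces with time along the first dimension.
#' @param sampling_rate,t0 required when `data` is a bare array.
#' @return same type and shape as the input.
#' @export
ubp_term <- function(data, sampling_rate = NULL, t0 = NULL) {
  if (inherits(data, "pact_sensor_data")) {
    out <- data
    out$samples <- ubp_term(data$samples, data$sampling_rate, data$t0)
    return(out)
  }
  if (is.null(sampling_rate) || is.null(t0))
    stop("sampling_rate and t0 are required for bare arrays", call. = FALSE)
  p <- data
  vec <- is.null(dim(p))
  if (vec) dim(p) <- c(length(p), 1L)
  d <- dim(p)
  nt <- d[1]
  if (nt < 2L)
    stop("need at least 2 time samples to form the derivative", call. = FALSE)
  fs <- sampling_rate
  flat <- matrix(p, nrow = nt)
  dp <- matrix(0, nrow = nt, ncol = ncol(flat))
  if (nt > 2L)
    dp[2:(nt - 1), ] <- (flat[3:nt, , drop = FALSE] -
                           flat[1:(nt - 2), , drop = FALSE]) * (fs / 2)
  dp[1, ] <- (flat[2, ] - flat[1, ]) * fs
  dp[nt, ] <- (flat[nt, ] - flat[nt - 1, ]) * fs
  t <- t0 + (seq_len(nt) - 1) / fs
  b <- 2 * flat - 2 * t * dp
  dim(b) <- d
  if (vec) dim(b) <- NULL
  b
}

#' Sample a trace at an arbitrary time by linear interpolation
#'
#' Evaluates a regularly sampled trace at time(s) `t` by linear interpolation
#' between the two bracketing samples; times outside the recorded window
#' `[t0, t_last]` return 0 (the trace is taken as silent outside its
#' support).  On-grid times reproduce the stored samples exactly.
#'
#' @param trace numeric vector of samples.
#' @param t time(s) in us; vectorized.
#' @param sampling_rate sampling rate in MHz.
#' @param t0 time of the first sample in us.
#' @return interpolated value(s), same length as `t`.
#' @export
sample_at <- function(trace, t, sampling_rate, t0 = 0) {
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0", call. = FALSE)
  nt <- length(trace)
  pos <- (t - t0) * sampling_rate
  out <- numeric(length(t))
  if (nt == 1L) {
    hit <- is.finite(pos) & pos == 0
    out[hit] <- trace[1]
    return(out)
  }
  ok <- is.finite(pos) & pos >= 0 & pos <= nt - 1
  if (any(ok)) {
    k <- pmin(floor(pos[ok]), nt - 2)
    f <- pos[ok] - k
    out[ok] <- trace[k + 1] * (1 - f) + trace[k + 2] * f
  }
  out
}

# Interpolate many delays into the traces of one (element, position) pair.
# tau is an array of times; returns same-shaped array, 0 outside support.
interp_trace <- function(trace, tau, sampling_rate, t0) {
  nt <- length(trace)
  pos <- (tau - t0) * sampling_rate
  ok <- pos >= 0 & pos <= nt - 1
  k <- pmin(floor(pos), nt - 2)
  k[!ok] <- 0
  f <- pos - k
  val <- (trace[k + 1] * (1 - f) + trace[k + 2] * f)
  val[!ok] <- 0
  val
}

#' Band-pass pre-filter for sinogram traces
#'
#' Optional zero-phase Butterworth band-pass applied per trace, for use when
#' the element bandwidth should be imposed before back-projection.  Off by
#' default in [reconstruct()]: the baseline pipeline back-projects the raw
#' integrand.
#'
#' @param data a [sensor_data()] object.
#' @param band length-2 numeric, pass band in MHz.
#' @param order Butterworth order (default 2).
#' @return filtered `pact_sensor_data`.
#' @export
bandpass_filter <- function(data, band, order = 2L) {
  if (!requireNamespace("signal", quietly = TRUE))
    stop("the 'signal' package is required for band-pass filtering",
         call. = FALSE)
  stopifnot(inherits(data, "pact_sensor_data"), length(band) == 2L)
  nyq <- data$sampling_rate / 2
  if (any(band <= 0) || any(band >= nyq) || band[1] >= band[2])
    stop("band must satisfy 0 < low < high < Nyquist", call. = FALSE)
  bf <- signal::butter(order, band / nyq, type = "pass")
  d <- dim(data$samples)
  flat <- matrix(data$samples, nrow = d[1])
  for (j in seq_len(ncol(flat)))
    flat[, j] <- signal::filtfilt(bf, flat[, j])
  out <- data
  out$samples <- array(flat, d)
  out
}
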