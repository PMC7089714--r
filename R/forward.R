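#' Sphere/point absorber phantom
#'
#' A phantom is a set of optical absorbers: spheres with a centre, radius and
#' initial-pressure amplitude.  Radius 0 marks an ideal point absorber,
#' rendered as a band-limited derivative-of-Gaussian pulse by the simulator.
#' Zero-mean white Gaussian noise of standard deviation `noise_sd` is added
#' to simulated traces, drawn reproducibly from `seed`.
#'
#' @param centers numeric matrix (n x 3) of absorber centres in mm
#'   (depth, lateral, elevation); may have zero rows.
#' @param radii absorber radii in mm (>= 0), recycled to n.
#' @param amplitudes initial pressure amplitudes, recycled to n.
#' @param noise_sd additive noise standard deviation (pressure units).
#' @param seed integer RNG seed for the noise draw.
#' @return An object of class `pact_phantom`.
#' @export
phantom <- function(centers, radii = 0, amplitudes = 1,
                    noise_sd = 0, seed = 1L) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  n <- nrow(centers)
  radii <- rep_len(as.numeric(radii), n)
  amplitudes <- rep_len(as.numeric(amplitudes), n)
  if (n > 0 && (any(!is.finite(radii)) || any(radii < 0)))
    stop("radii must be finite and >= 0", call. = FALSE)
  if (n > 0 && any(!is.finite(amplitudes)))
    stop("amplitudes must be finite", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(centers = centers, radii = radii, amplitudes = amplitudes,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "pact_phantom")
}

#' @export
print.pact_phantom <- function(x, ...) {
  cat(sprintf("Phantom: %d absorber(s), noise sd %g (seed %d)\n",
              nrow(x$centers), x$noise_sd, x$seed))
  invisible(x)
}

#' Tube phantom built from overlapping spheres
#'
#' Approximates a blood vessel as a chain of spheres along a polyline: the
#' polyline is resampled at `spacing` and a sphere of `radius` is placed at
#' every sample.  Overlap (`spacing <= radius`) makes the chain acoustically
#' continuous.
#'
#' @param control_points numeric matrix (k x 3) of polyline vertices in mm.
#' @param radius tube radius in mm (> 0).
#' @param spacing sphere spacing along the polyline in mm; must be
#'   `<= radius`.
#' @param amplitude initial pressure per sphere.
#' @inheritParams phantom
#' @return a [phantom()] whose spheres trace the tube.
#' @export
vessel_phantom <- function(control_points, radius, spacing = radius / 2,
                           amplitude = 1, noise_sd = 0, seed = 1L) {
  control_points <- matrix(as.numeric(control_points), ncol = 3)
  if (nrow(control_points) < 2L)
    stop("need at least two control points", call. = FALSE)
  if (!is.finite(radius) || radius <= 0)
    stop("radius must be > 0", call. = FALSE)
  if (!is.finite(spacing) || spacing <= 0 || spacing > radius)
    stop("spacing must be in (0, radius] so spheres overlap", call. = FALSE)
  seg <- diff(control_points)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = spacing)
  interp1 <- function(si) {
    j <- max(which(cum <= si + 1e-12))
    j <- min(j, nrow(control_points) - 1L)
    f <- if (len[j] > 0) (si - cum[j]) / len[j] else 0
    control_points[j, ] + f * seg[j, ]
  }
  centers <- t(vapply(s, interp1, numeric(3)))
  phantom(centers, radii = radius, amplitudes = amplitude,
          noise_sd = noise_sd, seed = seed)
}

#' Pressure trace of a uniformly heated spherical absorber
#'
#' Far-field analytic solution: a sphere of radius `a` at distance `d` emits
#' the classic N-shaped bipolar pulse
#' `p(t) = p0 (d - v_s t) / (2 d)` for `|d - v_s t| <= a`, zero elsewhere --
#' a leading compression peak `+p0 a / (2d)` at `t = (d - a)/v_s`, a zero
#' crossing at the centre `t = d/v_s`, and a trailing rarefaction.  Point
#' absorbers (`a = 0`) emit a band-limited derivative-of-Gaussian pulse of
#' width `pulse_sigma` with peak amplitude `p0 / (2 d)` scaling, centred at
#' the arrival time.
#'
#' @param d source-to-receiver distance in mm; must exceed `a`.
#' @param a sphere radius in mm (0 = ideal point).
#' @param p0 initial pressure amplitude.
#' @param v_s speed of sound in mm/us.
#' @param t time(s) in us; vectorized.
#' @param pulse_sigma Gaussian width in us for point absorbers.
#' @param arrival pulse-centre arrival time in us; defaults to `d / v_s`
#'   (straight-line propagation).  A focused-receiver delay model may supply
#'   its own arrival time; the pulse is then translated while amplitude still
#'   falls off with the physical distance `d`.
#' @return pressure value(s), same length as `t`.
#' @export
sphere_signal <- function(d, a, p0, v_s = 1.54, t, pulse_sigma = 0.0707,
                          arrival = d / v_s) {
  if (!is.finite(d) || d <= a)
    stop("receiver must be outside the absorber (d > a >= 0)", call. = FALSE)
  if (a < 0) stop("radius must be >= 0", call. = FALSE)
  # p0 multiplies last so amplitude scaling is exact, not just to rounding
  if (a > 0) {
    u <- v_s * (t - arrival)            # signed distance from shell centre
    # hair of slack so the support boundary |u| = a survives roundoff in t
    p0 * ifelse(abs(u) <= a * (1 + 1e-12), -u / (2 * d), 0)
  } else {
    u <- (t - arrival) / pulse_sigma
    p0 * (-u * exp((1 - u^2) / 2) / (2 * d))
  }
}

#' Simulate a sinogram from a phantom
#'
#' Each trace is the sum over absorbers of [sphere_signal()] evaluated at the
#' element's arrival time under the chosen delay model, so that the forward
#' model and the reconstruction share the same geometry, plus optional white
#' Gaussian noise drawn from the phantom's seed (fixed seed implies
#' bit-identical output).
#'
#' @param phantom a [phantom()].
#' @param geometry an [array_geometry()].
#' @param trajectory a [scan_trajectory()].
#' @param sampling_rate sampling rate in MHz; default 4x the element centre
#'   frequency.
#' @param t0 time of the first sample in us.
#' @param duration record length in us; must cover the farthest absorber.
#' @param model delay model, `"focal_line"` or `"point"`.
#' @param v_s speed of sound in mm/us.
#' @param pulse_sigma Gaussian width (us) for point absorbers; default
#'   `1 / (2 pi f_c)` puts the pulse's spectral peak at the element centre
#'   frequency.
#' @return a [sensor_data()] sinogram.
#' @export
simulate_sinogram <- function(phantom, geometry, trajectory,
                              sampling_rate = 4 * geometry$center_frequency,
                              t0 = 0, duration,
                              model = c("focal_line", "point"), v_s = 1.54,
                              pulse_sigma = 1 / (2 * pi * geometry$center_frequency)) {
  model <- match.arg(model)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0", call. = FALSE)
  nt <- as.integer(floor(duration * sampling_rate)) + 1L
  t <- t0 + (seq_len(nt) - 1) / sampling_rate
  t_end <- t[nt]
  ne <- geometry$n_elements
  np <- trajectory$n_positions
  ev <- elevation_positions(trajectory)
  ex <- geometry$element_lateral_positions
  samples <- array(0, c(nt, ne, np))
  for (j in seq_len(nrow(phantom$centers))) {
    ctr <- phantom$centers[j, ]
    a <- phantom$radii[j]
    p0 <- phantom$amplitudes[j]
    tau_rng <- c(Inf, -Inf)
    half <- if (a > 0) a / v_s else 4 * pulse_sigma
    for (si in seq_len(np)) {
      for (ei in seq_len(ne)) {
        elem <- c(0, ex[ei], ev[si])
        d <- sqrt(sum((ctr - elem)^2))
        tau <- if (model == "focal_line")
          focal_line_delay(ctr, elem, geometry$focal_length, v_s)
        else d / v_s
        tau_rng <- c(min(tau_rng[1], tau), max(tau_rng[2], tau))
        samples[, ei, si] <- samples[, ei, si] +
          sphere_signal(d, a, p0, v_s, t, pulse_sigma, arrival = tau)
      }
    }
    if (tau_rng[1] - half < t0 || tau_rng[2] + half > t_end)
      warning(sprintf(
        "absorber %d (centre %.3g, %.3g, %.3g mm) falls partly outside the time window [%g, %g] us",
        j, ctr[1], ctr[2], ctr[3], t0, t_end), call. = FALSE)
  }
  if (phantom$noise_sd > 0) {
    set.seed(phantom$seed)
    samples <- samples + array(stats::rnorm(length(samples),
                                            sd = phantom$noise_sd),
                               dim(samples))
  }
  sensor_data(samples, sampling_rate, t0)
}

#' Deterministic end-to-end test fixtures
#'
#' Bundles a phantom with a matching acquisition geometry, scan trajectory,
#' reconstruction grid and timing so forward simulation and reconstruction
#' can be exercised reproducibly:
#'
#' * `point_grid` -- three point absorbers under a small unfocused 16-element
#'   array; quick smoke-level end-to-end checks.
#' * `three_tubes` -- three sphere-chain "vessels" at different depths under
#'   a focused 32-element array; a vasculature-like scene for rendering.
#' * `paper_geometry_small` -- the validation acquisition scaled down for
#'   desk-scale runs: 128-element/2.25 MHz array geometry reduced to 32
#'   elements, 50 scan lines at the original 0.1 mm elevation step, RF 2
#'   grid, five point absorbers at distinct known positions.
#'
#' @param name one of `"point_grid"`, `"three_tubes"`,
#'   `"paper_geometry_small"`.
#' @return list with `phantom`, `geometry`, `trajectory`, `grid`, `v_s`,
#'   `sampling_rate`, `t0`, `duration`.
#' @export
fixture_suite <- function(name = c("point_grid", "three_tubes",
                                   "paper_geometry_small")) {
  name <- match.arg(name)
  v_s <- 1.54
  if (name == "point_grid") {
    geometry <- array_geometry(n_elements = 16L, pitch = 86 / 128,
                               focal_length = 0)
    trajectory <- scan_trajectory(step_size = 0.5, n_positions = 16L)
    grid <- build_grid(12, 12, 8, rf = 2)
    ph <- phantom(rbind(c(4.25, -2.75, 2.25),
                        c(6.75, 1.25, 3.75),
                        c(9.25, 3.25, 5.25)))
    list(phantom = ph, geometry = geometry, trajectory = trajectory,
         grid = grid, v_s = v_s, sampling_rate = 9, t0 = 0, duration = 16)
  } else if (name == "three_tubes") {
    geometry <- array_geometry(n_elements = 32L, pitch = 86 / 128,
                               focal_length = 15)
    trajectory <- scan_trajectory(step_size = 0.25, n_positions = 24L)
    grid <- build_grid(20, 22, 6, rf = 2)
    mk <- function(z, y) rbind(c(z, -8, y), c(z, 8, y))
    ph <- phantom(rbind(
      vessel_phantom(mk(6, 1.5), radius = 0.4, spacing = 0.3)$centers,
      vessel_phantom(mk(10, 3.0), radius = 0.4, spacing = 0.3)$centers,
      vessel_phantom(mk(14, 4.5), radius = 0.4, spacing = 0.3)$centers),
      radii = 0.4)
    list(phantom = ph, geometry = geometry, trajectory = trajectory,
         grid = grid, v_s = v_s, sampling_rate = 9, t0 = -6, duration = 32)
  } else {
    geometry <- array_geometry(n_elements = 32L, pitch = 86 / 128,
                               center_frequency = 2.25, focal_length = 15)
    trajectory <- scan_trajectory(step_size = 0.1, n_positions = 50L)
    grid <- build_grid(20, 20, 5, rf = 2)
    ph <- phantom(rbind(c(5.25, -4.75, 1.25),
                        c(8.25, 3.25, 2.25),
                        c(11.25, 0.25, 2.75),
                        c(14.25, 4.75, 3.25),
                        c(16.75, -3.25, 3.75)))
    # t0 < 0: under the focal-line model, sources in front of the focus have
    # arrival time (F - d)/v_s which can be negative; the record therefore
    # includes pre-trigger samples so those arrivals are captured.
    list(phantom = ph, geometry = geometry, trajectory = trajectory,
         grid = grid, v_s = v_s, sampling_rate = 9, t0 = -5, duration = 25)
  }
}
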