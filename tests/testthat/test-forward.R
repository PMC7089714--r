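test_that("the N-shaped sphere pulse matches its closed form", {
  d <- 10; a <- 1; p0 <- 2; v_s <- 1.54
  # zero crossing at the arrival of the sphere centre
  expect_identical(sphere_signal(d, a, p0, v_s, t = d / v_s), 0)
  # leading compression peak +p0 a / (2d) at t = (d - a)/v_s
  expect_equal(sphere_signal(d, a, p0, v_s, t = (d - a) / v_s),
               p0 * a / (2 * d))
  # trailing rarefaction mirror
  expect_equal(sphere_signal(d, a, p0, v_s, t = (d + a) / v_s),
               -p0 * a / (2 * d))
  # zero outside the support
  expect_identical(sphere_signal(d, a, p0, v_s,
                                 t = c((d - 2 * a) / v_s, (d + 2 * a) / v_s)),
                   c(0, 0))
  # odd symmetry about the centre: the time integral over the support is 0
  t <- seq((d - a) / v_s, (d + a) / v_s, length.out = 4001)
  p <- sphere_signal(d, a, p0, v_s, t)
  expect_lt(abs(sum(p) * (t[2] - t[1])), 1e-9)
  expect_error(sphere_signal(1, 2, p0, v_s, t = 0), "outside the absorber")
})

test_that("simulated point-source arrivals land at the delay model's times", {
  fx <- fixture_suite("point_grid")
  one <- phantom(matrix(c(6.75, 1.25, 3.75), 1))
  sino <- simulate_sinogram(one, fx$geometry, fx$trajectory,
                            sampling_rate = fx$sampling_rate, t0 = fx$t0,
                            duration = fx$duration, model = "point",
                            v_s = fx$v_s)
  t <- time_axis(sino)
  for (ei in c(1L, 8L, 16L)) for (si in c(1L, 9L, 16L)) {
    elem <- element_position(fx$geometry, fx$trajectory, ei, si)
    tau <- point_delay(c(6.75, 1.25, 3.75), elem, fx$v_s)
    k <- which.max(abs(sino$samples[, ei, si]))
    expect_lt(abs(t[k] - tau) * sino$sampling_rate, 1.5)
  }
})

test_that("simulation is linear in amplitude and additive over absorbers", {
  fx <- fixture_suite("point_grid")
  args <- list(geometry = fx$geometry, trajectory = fx$trajectory,
               sampling_rate = fx$sampling_rate, t0 = fx$t0,
               duration = fx$duration, model = "point", v_s = fx$v_s)
  empty <- do.call(simulate_sinogram, c(list(phantom(matrix(0, 0, 3))), args))
  expect_true(all(empty$samples == 0))

  c1 <- fx$phantom$centers[1, , drop = FALSE]
  c2 <- fx$phantom$centers[2, , drop = FALSE]
  s1 <- do.call(simulate_sinogram, c(list(phantom(c1)), args))
  s2 <- do.call(simulate_sinogram, c(list(phantom(c2)), args))
  s12 <- do.call(simulate_sinogram, c(list(phantom(rbind(c1, c2))), args))
  expect_equal(s12$samples, s1$samples + s2$samples)

  s3 <- do.call(simulate_sinogram, c(list(phantom(c1, amplitudes = 3)), args))
  expect_identical(s3$samples, 3 * s1$samples)
})

test_that("noise is reproducible by seed and differs across seeds", {
  fx <- fixture_suite("point_grid")
  mk <- function(seed) {
    ph <- phantom(fx$phantom$centers, noise_sd = 0.1, seed = seed)
    simulate_sinogram(ph, fx$geometry, fx$trajectory,
                      sampling_rate = fx$sampling_rate, t0 = fx$t0,
                      duration = fx$duration, model = "point", v_s = fx$v_s)
  }
  expect_identical(mk(123L)$samples, mk(123L)$samples)
  expect_false(identical(mk(123L)$samples, mk(124L)$samples))
})

test_that("an absorber outside the record window is reported by index", {
  fx <- fixture_suite("point_grid")
  far <- phantom(rbind(fx$phantom$centers[1, ], c(60, 0, 4)))
  expect_warning(
    simulate_sinogram(far, fx$geometry, fx$trajectory,
                      sampling_rate = fx$sampling_rate, t0 = fx$t0,
                      duration = fx$duration, model = "point", v_s = fx$v_s),
    "absorber 2")
  expect_error(
    simulate_sinogram(fx$phantom, fx$geometry, fx$trajectory,
                      duration = -1), "duration")
})

test_that("vessel phantoms resample the polyline with overlapping spheres", {
  pts <- rbind(c(10, -4, 2), c(10, 4, 2), c(14, 4, 5))
  vp <- vessel_phantom(pts, radius = 0.5, spacing = 0.4)
  gaps <- sqrt(rowSums(diff(vp$centers)^2))
  expect_true(all(gaps <= 0.5 + 1e-9))          # continuous tube
  expect_equal(vp$centers[1, ], c(10, -4, 2))   # starts at the first vertex
  expect_true(all(vp$radii == 0.5))
  expect_error(vessel_phantom(pts, radius = 0.3, spacing = 0.4), "overlap")
})

test_that("fixture suite bundles are internally consistent", {
  for (nm in c("point_grid", "three_tubes", "paper_geometry_small")) {
    fx <- fixture_suite(nm)
    expect_s3_class(fx$geometry, "pact_geometry")
    expect_s3_class(fx$grid, "pact_grid")
    ax <- grid_axes(fx$grid)
    ctr <- fx$phantom$centers
    expect_true(all(ctr[, 1] >= min(ax$depth) & ctr[, 1] <= max(ax$depth)))
    expect_true(all(ctr[, 3] >= min(ax$elevation) &
                      ctr[, 3] <= max(ax$elevation)))
  }
  fx <- fixture_suite("paper_geometry_small")
  expect_identical(fx$geometry$n_elements, 32L)
  expect_identical(fx$trajectory$n_positions, 50L)
  expect_equal(fx$grid$rf, 2)
})
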