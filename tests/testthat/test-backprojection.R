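test_that("reconstruction is linear and maps silence to silence", {
  su <- tiny_setup(focal_length = 5)
  zero <- tiny_sinogram(su)
  zero$samples[] <- 0
  vol <- reconstruct(zero, su$geometry, su$trajectory, su$grid)
  expect_true(all(vol$values == 0))

  a <- tiny_sinogram(su, seed = 3)
  b <- tiny_sinogram(su, seed = 4)
  ab <- a
  ab$samples <- a$samples + b$samples
  va <- reconstruct(a, su$geometry, su$trajectory, su$grid)
  vb <- reconstruct(b, su$geometry, su$trajectory, su$grid)
  vab <- reconstruct(ab, su$geometry, su$trajectory, su$grid)
  expect_rel_equal(vab$values, va$values + vb$values, 1e-10)
})

test_that("degenerate single-trace reconstruction matches hand evaluation", {
  geometry <- array_geometry(n_elements = 1L, pitch = 1)
  trajectory <- scan_trajectory(n_positions = 1L)
  grid <- build_grid(3, 2, 1, rf = 1)
  # two time samples so the derivative exists; das integrand for transparency
  data <- sensor_data(array(c(4, 4), c(2, 1, 1)), sampling_rate = 1, t0 = 0)
  vol <- reconstruct(data, geometry, trajectory, grid, model = "point",
                     integrand = "das", v_s = 1)
  for (iz in 1:3) for (ix in 1:2) {
    v <- voxel_center(grid, c(iz, ix, 1))
    tau <- point_delay(v, c(0, 0, 0), 1)
    expect_equal(vol$values[iz, ix, 1],
                 sample_at(c(4, 4), tau, 1, 0))   # w = 1/(1 pair) = 1
  }
})

test_that("vectorized core equals the loop reference on random instances", {
  set.seed(2024)
  for (k in 1:8) {
    inst <- random_small_instance()
    fast <- do.call(reconstruct, inst)
    slow <- do.call(reconstruct_reference, inst)
    expect_rel_equal(fast$values, slow$values, 1e-9)
  }
})

test_that("aperture masking agrees between core and reference", {
  su <- tiny_setup(focal_length = 4)
  data <- tiny_sinogram(su, seed = 9)
  for (w in c("uniform", "solid_angle")) {
    fast <- reconstruct(data, su$geometry, su$trajectory, su$grid,
                        weighting = w, aperture_half_angle = 30)
    slow <- reconstruct_reference(data, su$geometry, su$trajectory, su$grid,
                                  weighting = w, aperture_half_angle = 30)
    expect_rel_equal(fast$values, slow$values, 1e-9)
    open <- reconstruct(data, su$geometry, su$trajectory, su$grid,
                        weighting = w)
    expect_gt(max(abs(open$values - fast$values)), 0)  # the cut does something
  }
})

test_that("depth-slab tiling does not change the result", {
  su <- tiny_setup(n_elements = 6L, n_positions = 4L, focal_length = 7)
  data <- tiny_sinogram(su, nt = 40L, seed = 5)
  whole <- reconstruct(data, su$geometry, su$trajectory, su$grid,
                       tile_bytes = 1e9)
  sliced <- reconstruct(data, su$geometry, su$trajectory, su$grid,
                        tile_bytes = 8 * 8 * prod(su$grid$dims[2:3]))
  expect_identical(whole$values, sliced$values)
})

test_that("progress reporting fires per scan line and changes nothing", {
  su <- tiny_setup(n_positions = 5L)
  data <- tiny_sinogram(su, seed = 6)
  seen <- integer()
  withp <- reconstruct(data, su$geometry, su$trajectory, su$grid,
                       progress = function(i, n) seen <<- c(seen, i))
  expect_identical(seen, 1:5)
  without <- reconstruct(data, su$geometry, su$trajectory, su$grid)
  expect_identical(withp$values, without$values)
})

test_that("shape mismatches and non-finite samples are rejected by name", {
  su <- tiny_setup()
  data <- tiny_sinogram(su)
  wrong <- sensor_data(data$samples[, 1:2, ], data$sampling_rate)
  expect_error(reconstruct(wrong, su$geometry, su$trajectory, su$grid),
               "does not match")
  bad <- data
  bad$samples[3, 2, 1] <- NaN
  expect_error(reconstruct(bad, su$geometry, su$trajectory, su$grid),
               "time 3, element 2, position 1")
})

test_that("translating a point source translates the reconstruction argmax", {
  # wide unfocused array approximating an open aperture, point model
  geometry <- array_geometry(n_elements = 24L, pitch = 1)
  trajectory <- scan_trajectory(step_size = 1, n_positions = 12L,
                                start_offset = -2)
  grid <- build_grid(8, 8, 8, rf = 1)
  base <- c(3.5, -0.5, 3.5)
  shift <- c(0, 1, 0)   # one voxel pitch along lateral
  vols <- lapply(list(base, base + shift), function(ctr) {
    sino <- simulate_sinogram(phantom(matrix(ctr, 1)), geometry, trajectory,
                              sampling_rate = 10, duration = 16,
                              model = "point")
    reconstruct(sino, geometry, trajectory, grid, model = "point")
  })
  am <- lapply(vols, function(v) arrayInd(which.max(abs(v$values)),
                                          dim(v$values)))
  expect_identical(am[[2]] - am[[1]], matrix(c(0L, 1L, 0L), 1))
})
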