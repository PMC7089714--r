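test_that("point delay matches a literal distance computation", {
  expect_identical(point_delay(c(1, 2, 3), c(1, 2, 3)), 0)
  # |r| = 15.4 mm at 1.54 mm/us is 10 us
  expect_equal(point_delay(c(15.4, 0, 0), c(0, 0, 0), v_s = 1.54), 10)

  set.seed(7)
  for (k in 1:100) {
    a <- rnorm(3, sd = 10); b <- rnorm(3, sd = 10); v <- runif(1, 1, 2)
    brute <- sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2) / v
    expect_equal(point_delay(a, b, v), brute)
    expect_equal(point_delay(a, b, v), point_delay(b, a, v))  # symmetry
  }
  expect_error(point_delay(c(0, 0, 0), c(1, 0, 0), v_s = 0), "v_s")
})

test_that("focal-line delay follows the virtual-point-detector geometry", {
  elem <- c(0, 1.2, 3.4)
  # unfocused limit is exactly the point model
  for (v in list(c(5, 0, 0), c(0.5, 2, 1), c(9, -3, 7))) {
    expect_identical(focal_line_delay(v, elem, 0, 1.54),
                     point_delay(v, elem, 1.54))
  }
  # voxel at the virtual detector: delay = F / v_s
  F <- 12
  expect_equal(focal_line_delay(c(F, elem[2], elem[3]), elem, F, 1.54),
               F / 1.54)
  # on-axis beyond the focus: straight-line path z / v_s
  expect_equal(focal_line_delay(c(20, elem[2], elem[3]), elem, F, 1.54),
               20 / 1.54)
  # on-axis before the focus too
  expect_equal(focal_line_delay(c(5, elem[2], elem[3]), elem, F, 1.54),
               5 / 1.54)
  expect_error(focal_line_delay(c(1, 0, 0), elem, -1), "focal_length")
})

test_that("focal-line delay is continuous and monotone along the element axis", {
  elem <- c(0, -0.7, 2)
  F <- 10
  z <- seq(0.01, 25, length.out = 2000)
  tau <- vapply(z, function(zz)
    focal_line_delay(c(zz, elem[2], elem[3]), elem, F, 1.54), numeric(1))
  expect_true(all(diff(tau) > 0))                       # strictly increasing
  expect_lt(max(abs(diff(tau))), 2 * (z[2] - z[1]) / 1.54 + 1e-12)  # no jump
})

test_that("focal-line delay converges to the point delay as F -> 0", {
  elem <- c(0, 0.5, 1)
  set.seed(11)
  vox <- matrix(c(runif(20, 1, 15), runif(20, -8, 8), runif(20, -2, 6)), 20)
  worst <- vapply(c(1, 0.1, 0.01, 0), function(F) {
    max(vapply(seq_len(20), function(i)
      abs(focal_line_delay(vox[i, ], elem, F, 1.54) -
            point_delay(vox[i, ], elem, 1.54)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(worst) < 0 | worst[-1] == 0))  # shrinks monotonically
  expect_identical(worst[4], 0)                        # exact at F = 0
})

test_that("vectorized delay tables equal scalar calls entry by entry", {
  su <- tiny_setup(n_elements = 3L, n_positions = 2L, focal_length = 6)
  for (model in c("point", "focal_line")) {
    tab <- delay_table(su$grid, su$geometry, su$trajectory, model = model,
                       v_s = 1.5)
    for (ei in 1:3) for (si in 1:2) {
      elem <- element_position(su$geometry, su$trajectory, ei, si)
      for (iz in seq_len(su$grid$dims[1]))
        for (ix in seq_len(su$grid$dims[2]))
          for (iy in seq_len(su$grid$dims[3])) {
            v <- voxel_center(su$grid, c(iz, ix, iy))
            want <- if (model == "focal_line")
              focal_line_delay(v, elem, su$geometry$focal_length, 1.5)
            else point_delay(v, elem, 1.5)
            expect_lt(abs(tab[iz, ix, iy, ei, si] - want), 1e-9)
          }
    }
  }
})

test_that("delay_table refuses requests beyond the memory budget", {
  g <- build_grid(40, 86, 40, rf = 5)
  expect_error(
    delay_table(g, array_geometry(), scan_trajectory(), max_bytes = 1e9),
    "budget")
  # a restricted request fits
  tab <- delay_table(build_grid(2, 2, 2, 1), array_geometry(),
                     scan_trajectory(), elements = 1:2, positions = 1L)
  expect_identical(dim(tab), c(2L, 2L, 2L, 2L, 1L))
})
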