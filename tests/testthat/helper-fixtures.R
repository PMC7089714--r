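# Small shared helpers: every fixture is built in code at test time.

# a tiny deterministic acquisition used by several files
tiny_setup <- function(n_elements = 4L, n_positions = 3L, focal_length = 0) {
  list(
    geometry = array_geometry(n_elements = n_elements, pitch = 0.8,
                              focal_length = focal_length),
    trajectory = scan_trajectory(step_size = 0.5, n_positions = n_positions),
    grid = build_grid(4, 4, 2, rf = 1))
}

# deterministic random sinogram matching a setup
tiny_sinogram <- function(setup, nt = 24L, fs = 8, t0 = 0, seed = 42L) {
  set.seed(seed)
  sensor_data(array(rnorm(nt * setup$geometry$n_elements *
                            setup$trajectory$n_positions),
                    c(nt, setup$geometry$n_elements,
                      setup$trajectory$n_positions)),
              sampling_rate = fs, t0 = t0)
}

expect_rel_equal <- function(a, b, tol) {
  scale <- max(abs(b), 1e-300)
  expect_lt(max(abs(a - b)) / scale, tol)
}
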