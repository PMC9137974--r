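# Shared fixtures: one average-adult reference model and device, rebuilt
# once per test run, plus small random-geometry generators.

default_ref <- ankle_reference(H = 175)
default_model <- ankle_model(default_ref)
default_geom <- default_device_geometry(default_ref)

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation <- function() {
  rodrigues_rotation(random_unit(), stats::runif(1, -pi, pi))
}

# angle between two directions, sign-insensitive, in radians
dir_angle <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
}

expect_vec_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual - expected)), tol)
}
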