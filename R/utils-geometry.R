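# Small 3-vector / rotation helpers shared across modules.
# Lengths are centimetres, angles degrees at the API boundary and radians
# internally throughout the package.

abort_ankle <- function(message, class, ...) {
  stop(structure(
    class = c(paste0("anklekin_", class), "anklekin_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

as_vec3 <- function(x, name = "vector") {
  x <- as.numeric(x)
  if (length(x) != 3L || !all(is.finite(x))) {
    abort_ankle(sprintf("`%s` must be a finite numeric 3-vector", name),
                "invalid_parameter")
  }
  x
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v, name = "vector") {
  n <- norm3(v)
  if (n < 1e-12) {
    abort_ankle(sprintf("cannot normalize `%s`: zero length", name),
                "degenerate_geometry")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Elementary active right-handed rotations about the coordinate axes (radians).
rot_axis <- function(axis, theta) {
  c_ <- cos(theta)
  s_ <- sin(theta)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3L, 3L),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3L, 3L),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3L, 3L),
    abort_ankle("rotation axis must be one of 'x', 'y', 'z'", "invalid_parameter")
  )
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_ankle(sprintf("`%s` must be a single positive finite number", name),
                "invalid_parameter")
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort_ankle(sprintf("`%s` must be a single non-negative finite number", name),
                "invalid_parameter")
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Row-wise Euclidean distance from an n x 3 matrix to a point.
dist_to_point <- function(pts, p) {
  pts <- rbind(pts)
  sqrt((pts[, 1L] - p[1L])^2 + (pts[, 2L] - p[2L])^2 + (pts[, 3L] - p[3L])^2)
}
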