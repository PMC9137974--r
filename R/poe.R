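#' Skew-symmetric (hat) matrix of a 3-vector
#'
#' Returns the matrix `Omega` with `Omega %*% v == cross(omega, v)`.
#'
#' @param omega 3-vector.
#' @return 3x3 antisymmetric matrix.
#' @export
skew <- function(omega) {
  omega <- as_vec3(omega, "omega")
  matrix(c(0, omega[3L], -omega[2L],
           -omega[3L], 0, omega[1L],
           omega[2L], -omega[1L], 0), 3L, 3L)
}

check_unit_axis <- function(omega, tol = 1e-6) {
  omega <- as_vec3(omega, "omega")
  if (abs(norm3(omega) - 1) > tol) {
    abort_ankle("`omega` must be a unit vector", "invalid_axis")
  }
  omega
}

#' Rodrigues rotation matrix
#'
#' `R = I + Omega * sin(theta) + Omega^2 * (1 - cos(theta))` for a unit axis
#' `omega` (with `Omega = skew(omega)`); the matrix exponential of
#' `theta * Omega`.
#'
#' @param omega Unit 3-vector rotation axis.
#' @param theta Angle in radians.
#' @return Proper 3x3 rotation matrix.
#' @export
rodrigues_rotation <- function(omega, theta) {
  omega <- check_unit_axis(omega)
  Om <- skew(omega)
  diag(3L) + Om * sin(theta) + (Om %*% Om) * (1 - cos(theta))
}

#' Twist of a revolute joint through a point
#'
#' For a revolute axis with unit direction `omega` passing through the point
#' `r`, the screw generator has translational part `nu = -omega x r`.
#'
#' @param omega Unit 3-vector axis direction.
#' @param r 3-vector point on the axis (cm).
#' @return An object of class `ankle_twist` with fields `omega`, `nu` and the
#'   generating `point`.
#' @export
twist_from_axis <- function(omega, r) {
  omega <- check_unit_axis(omega)
  r <- as_vec3(r, "r")
  structure(list(omega = omega, nu = -cross3(omega, r), point = r),
            class = "ankle_twist")
}

#' @export
print.ankle_twist <- function(x, ...) {
  cat(sprintf("Twist: omega = (%.4f, %.4f, %.4f), nu = (%.4f, %.4f, %.4f)\n",
              x$omega[1], x$omega[2], x$omega[3],
              x$nu[1], x$nu[2], x$nu[3]))
  invisible(x)
}

new_pose <- function(R, p) {
  structure(list(R = R, p = as.numeric(p)), class = "ankle_pose")
}

#' Identity rigid transform
#' @return An `ankle_pose` with identity rotation and zero translation.
#' @export
identity_pose <- function() new_pose(diag(3L), c(0, 0, 0))

#' @export
print.ankle_pose <- function(x, ...) {
  cat("Rigid transform (rotation | translation cm):\n")
  m <- cbind(x$R, x$p)
  dimnames(m) <- list(NULL, c("", "", "", "t"))
  print(round(m, 6))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' @param a,b `ankle_pose` objects; returns the transform "a then applied
#'   after b", i.e. `(a %o% b)(x) = a(b(x))`.
#' @return An `ankle_pose`.
#' @export
pose_compose <- function(a, b) {
  new_pose(a$R %*% b$R, drop(a$R %*% b$p) + a$p)
}

#' Apply a rigid transform to points
#'
#' @param pose An `ankle_pose`.
#' @param pts 3-vector or n x 3 matrix of points (cm).
#' @return Transformed points, same shape as the input.
#' @export
pose_apply <- function(pose, pts) {
  if (is.null(dim(pts))) {
    drop(pose$R %*% as_vec3(pts, "pts")) + pose$p
  } else {
    sweep(pts %*% t(pose$R), 2L, pose$p, "+")
  }
}

#' Inverse of a rigid transform
#' @param pose An `ankle_pose`.
#' @return The inverse `ankle_pose`.
#' @export
pose_inverse <- function(pose) {
  Rt <- t(pose$R)
  new_pose(Rt, drop(-Rt %*% pose$p))
}

#' Exponential of a twist
#'
#' Screw motion of angle `theta` about the twist's axis: rotation by the
#' Rodrigues formula and translation
#' `p = (I - R) (omega x nu) + omega omega^T nu theta` (zero for a revolute
#' twist, whose `nu` is orthogonal to `omega`).
#'
#' @param xi An `ankle_twist`.
#' @param theta Angle in radians.
#' @return An `ankle_pose`.
#' @export
twist_exponential <- function(xi, theta) {
  R <- rodrigues_rotation(xi$omega, theta)
  p <- drop((diag(3L) - R) %*% cross3(xi$omega, xi$nu)) +
    xi$omega * sum(xi$omega * xi$nu) * theta
  new_pose(R, p)
}

#' Two-axis ankle model
#'
#' Bundles the talocrural (TC) and subtalar (ST) twists, the joint angle
#' ranges and the tracked initial points (platform vertices and centre) into
#' the forward-kinematic model
#' `g(theta1, theta2) = exp(xi_tc theta1) exp(xi_st theta2)`, TC applied
#' outermost.
#'
#' @param ref An [ankle_reference()]; used for axes and platform points unless
#'   overridden.
#' @param theta1_range,theta2_range Joint ranges in degrees (length-2,
#'   increasing).
#' @param twist_tc,twist_st Optional `ankle_twist` overrides.
#' @param points Optional named list of tracked 3-vectors (defaults
#'   `A0`, `B0`, `C0`, `PM` from `ref`).
#' @return An object of class `ankle_model`.
#' @examples
#' m <- ankle_model(ankle_reference(H = 175))
#' forward_kinematics(m, 0.1, -0.05, m$points$A0)
#' @export
ankle_model <- function(ref = ankle_reference(),
                        theta1_range = c(-15, 15), theta2_range = c(-15, 15),
                        twist_tc = NULL, twist_st = NULL, points = NULL) {
  for (nm in c("theta1_range", "theta2_range")) {
    r <- get(nm)
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] > r[2L]) {
      abort_ankle(sprintf("`%s` must be a non-decreasing length-2 interval (deg)", nm),
                  "invalid_parameter")
    }
  }
  if (is.null(twist_tc)) twist_tc <- twist_from_axis(ref$omega_tc, ref$r1)
  if (is.null(twist_st)) twist_st <- twist_from_axis(ref$omega_st, ref$r2)
  if (is.null(points)) {
    points <- list(A0 = ref$A0, B0 = ref$B0, C0 = ref$C0, PM = ref$PM)
  }
  structure(list(twist_tc = twist_tc, twist_st = twist_st,
                 theta1_range = theta1_range, theta2_range = theta2_range,
                 points = lapply(points, as_vec3), reference = ref),
            class = "ankle_model")
}

#' @export
print.ankle_model <- function(x, ...) {
  cat("Biaxial ankle model (product of exponentials, TC then ST)\n")
  cat(sprintf("  theta1 (TC) range: [%g, %g] deg; theta2 (ST) range: [%g, %g] deg\n",
              x$theta1_range[1], x$theta1_range[2],
              x$theta2_range[1], x$theta2_range[2]))
  cat("  TC "); print(x$twist_tc)
  cat("  ST "); print(x$twist_st)
  cat(sprintf("  tracked points: %s\n", paste(names(x$points), collapse = ", ")))
  invisible(x)
}

#' Platform pose at a joint configuration
#'
#' @param model An [ankle_model()].
#' @param theta1,theta2 TC and ST joint angles in radians.
#' @return The composed `ankle_pose` `exp(xi_tc theta1) exp(xi_st theta2)`.
#' @export
fk_pose <- function(model, theta1, theta2) {
  pose_compose(twist_exponential(model$twist_tc, theta1),
               twist_exponential(model$twist_st, theta2))
}

#' Forward kinematics of a tracked point
#'
#' @inheritParams fk_pose
#' @param point0 Initial 3-vector of the tracked point (cm).
#' @return The displaced 3-vector.
#' @export
forward_kinematics <- function(model, theta1, theta2, point0) {
  pose_apply(fk_pose(model, theta1, theta2), as_vec3(point0, "point0"))
}

#' Platform vertices at a joint configuration
#'
#' @inheritParams fk_pose
#' @return 3 x 3 matrix with rows `A`, `B`, `C` (cm).
#' @export
fk_vertices <- function(model, theta1, theta2) {
  g <- fk_pose(model, theta1, theta2)
  out <- rbind(A = pose_apply(g, model$points$A0),
               B = pose_apply(g, model$points$B0),
               C = pose_apply(g, model$points$C0))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Sample the reachable workspace on a joint-angle grid
#'
#' Evaluates the forward kinematics of each tracked point on a tensor grid
#' over the model's joint ranges.
#'
#' @param model An [ankle_model()].
#' @param n1,n2 Grid sizes (>= 2) along theta1 and theta2.
#' @param points Names of tracked points to evaluate.
#' @return A data.frame with columns `theta1`, `theta2` (degrees), `point`,
#'   `x`, `y`, `z` (cm).
#' @export
workspace_sample <- function(model, n1 = 31L, n2 = 31L,
                             points = names(model$points)) {
  if (n1 < 2L || n2 < 2L) {
    abort_ankle("grid sizes must be at least 2", "invalid_parameter")
  }
  t1 <- seq(model$theta1_range[1L], model$theta1_range[2L], length.out = n1)
  t2 <- seq(model$theta2_range[1L], model$theta2_range[2L], length.out = n2)
  grid <- expand.grid(theta1 = t1, theta2 = t2, KEEP.OUT.ATTRS = FALSE)
  out <- lapply(points, function(nm) {
    p0 <- model$points[[nm]]
    xyz <- t(vapply(seq_len(nrow(grid)), function(i) {
      forward_kinematics(model, deg2rad(grid$theta1[i]), deg2rad(grid$theta2[i]), p0)
    }, numeric(3L)))
    data.frame(theta1 = grid$theta1, theta2 = grid$theta2, point = nm,
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Maximal wire length over a workspace
#'
#' Triangle-inequality bound used to size the draw-wire sensors: the largest
#' sampled distance from the tracked point to the module anchor plus the
#' module radius `rm`.
#'
#' @param workspace n x 3 matrix (or data.frame with x, y, z columns) of
#'   sampled positions (cm).
#' @param anchor Module anchor 3-vector (cm).
#' @param rm Module radius in cm (non-negative).
#' @return Length in cm.
#' @export
max_wire_length <- function(workspace, anchor, rm = 0) {
  if (is.data.frame(workspace)) {
    workspace <- as.matrix(workspace[, c("x", "y", "z")])
  }
  if (is.null(dim(workspace)) || nrow(workspace) == 0L) {
    abort_ankle("`workspace` must contain at least one point",
                "invalid_parameter")
  }
  check_nonnegative(rm, "rm")
  max(dist_to_point(workspace, as_vec3(anchor, "anchor"))) + rm
}
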