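# Chart utilities: the tracked-point surface p(theta1, theta2) is a smooth
# two-parameter surface; its first fundamental form supplies a Riemannian
# metric on the joint-angle chart, and free ankle motion maps to geodesics.

fk_point <- function(model, th, point) {
  forward_kinematics(model, th[1L], th[2L], point)
}

range_rad <- function(model) {
  list(t1 = deg2rad(model$theta1_range), t2 = deg2rad(model$theta2_range))
}

check_interior <- function(model, theta1, theta2, h) {
  r <- range_rad(model)
  if (h <= 0 || h > min(diff(r$t1), diff(r$t2)) / 4) {
    abort_ankle("finite-difference step `h` must be positive and small relative to the joint ranges",
                "invalid_parameter")
  }
  if (theta1 - h < r$t1[1L] || theta1 + h > r$t1[2L] ||
      theta2 - h < r$t2[1L] || theta2 + h > r$t2[2L]) {
    abort_ankle("(theta1, theta2) must be interior to the joint ranges (with room for the step)",
                "invalid_parameter")
  }
  invisible(TRUE)
}

#' Induced metric of the tracked-point surface
#'
#' First fundamental form `g_ij = <dp/dtheta_i, dp/dtheta_j>` of the surface
#' traced by a tracked point as the two joint angles vary, evaluated by
#' central finite differences.
#'
#' @param model An [ankle_model()].
#' @param theta1,theta2 Chart coordinates in radians (interior to the ranges).
#' @param point Name of the tracked point (default the platform centre `PM`).
#' @param h Finite-difference step in radians.
#' @return Symmetric 2x2 matrix (cm^2 per rad^2).
#' @export
induced_metric <- function(model, theta1, theta2, point = "PM", h = 1e-4) {
  check_interior(model, theta1, theta2, h)
  p0 <- model$points[[point]]
  if (is.null(p0)) abort_ankle("unknown tracked point", "invalid_parameter")
  d1 <- (fk_point(model, c(theta1 + h, theta2), p0) -
         fk_point(model, c(theta1 - h, theta2), p0)) / (2 * h)
  d2 <- (fk_point(model, c(theta1, theta2 + h), p0) -
         fk_point(model, c(theta1, theta2 - h), p0)) / (2 * h)
  g12 <- sum(d1 * d2)
  matrix(c(sum(d1 * d1), g12, g12, sum(d2 * d2)), 2L, 2L)
}

christoffel_fd <- function(model, th, point, h) {
  # Gamma^k_ij = 1/2 g^{kl} (d_i g_jl + d_j g_il - d_l g_ij), derivatives by
  # central differences of the induced metric.
  g <- induced_metric(model, th[1L], th[2L], point = point, h = h)
  ginv <- solve(g)
  dg <- array(0, c(2L, 2L, 2L)) # dg[l, i, j] = d g_ij / d theta_l
  for (l in 1:2) {
    e <- c(0, 0); e[l] <- h
    gp <- induced_metric(model, th[1L] + e[1L], th[2L] + e[2L], point = point, h = h)
    gm <- induced_metric(model, th[1L] - e[1L], th[2L] - e[2L], point = point, h = h)
    dg[l, , ] <- (gp - gm) / (2 * h)
  }
  Gam <- array(0, c(2L, 2L, 2L)) # Gam[k, i, j]
  for (k in 1:2) for (i in 1:2) for (j in 1:2) {
    s <- 0
    for (l in 1:2) {
      s <- s + ginv[k, l] * (dg[i, j, l] + dg[j, i, l] - dg[l, i, j])
    }
    Gam[k, i, j] <- s / 2
  }
  Gam
}

#' Trace a geodesic of the joint-angle chart
#'
#' Integrates the geodesic equations of the induced metric with a fixed-step
#' fourth-order Runge-Kutta scheme; Christoffel symbols are evaluated by
#' finite differences of the metric. A geodesic is the path of the tracked
#' point under an initial velocity and no external forcing. If the path
#' leaves the chart the trace is truncated and flagged.
#'
#' @param model An [ankle_model()].
#' @param start Length-2 start coordinates (radians).
#' @param velocity Length-2 initial angular velocity (rad per unit time).
#' @param t_end Integration end time.
#' @param n_steps Number of RK4 steps (>= 1).
#' @param point Tracked point defining the surface.
#' @param h Finite-difference step for metric derivatives (radians).
#' @return A list with `path` (matrix of `t`, `theta1`, `theta2`, `dtheta1`,
#'   `dtheta2`), and `complete` (FALSE if truncated at the chart boundary).
#' @export
geodesic_trace <- function(model, start, velocity, t_end, n_steps = 1000L,
                           point = "PM", h = 1e-4) {
  if (n_steps < 1L) abort_ankle("`n_steps` must be >= 1", "invalid_parameter")
  start <- as.numeric(start); velocity <- as.numeric(velocity)
  check_interior(model, start[1L], start[2L], h)
  r <- range_rad(model)
  # integrate slightly inside the chart so the FD stencils stay valid
  inside <- function(th) {
    th[1L] - 3 * h >= r$t1[1L] && th[1L] + 3 * h <= r$t1[2L] &&
      th[2L] - 3 * h >= r$t2[1L] && th[2L] + 3 * h <= r$t2[2L]
  }
  deriv <- function(state) {
    th <- state[1:2]; v <- state[3:4]
    Gam <- christoffel_fd(model, th, point, h)
    acc <- numeric(2L)
    for (k in 1:2) acc[k] <- -drop(t(v) %*% Gam[k, , ] %*% v)
    c(v, acc)
  }
  dt <- t_end / n_steps
  state <- c(start, velocity)
  path <- matrix(NA_real_, n_steps + 1L, 5L,
                 dimnames = list(NULL, c("t", "theta1", "theta2",
                                         "dtheta1", "dtheta2")))
  path[1L, ] <- c(0, state)
  complete <- TRUE
  n_done <- 0L
  for (i in seq_len(n_steps)) {
    if (all(velocity == 0)) { # stationary path, skip the integrator
      path[i + 1L, ] <- c(i * dt, state)
      n_done <- i
      next
    }
    cand <- tryCatch({
      k1 <- deriv(state)
      k2 <- deriv(state + dt / 2 * k1)
      k3 <- deriv(state + dt / 2 * k2)
      k4 <- deriv(state + dt * k3)
      state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }, anklekin_invalid_parameter = function(e) NULL) # stage left the chart
    if (is.null(cand) || !inside(cand[1:2])) {
      complete <- FALSE
      break
    }
    state <- cand
    path[i + 1L, ] <- c(i * dt, state)
    n_done <- i
  }
  list(path = path[seq_len(n_done + 1L), , drop = FALSE], complete = complete)
}
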