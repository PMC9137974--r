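#' Vertex trajectory
#'
#' An ordered series of 3D positions of one tracked platform point during one
#' movement trial.
#'
#' @param points n x 3 matrix of positions (cm), n >= 3.
#' @param label Point label, one of `"A"`, `"B"`, `"C"`, `"PM"`.
#' @param movement Movement group, `"plantar_dorsiflexion"` (TC-dominant) or
#'   `"inversion_eversion"` (ST-dominant).
#' @return An object of class `ankle_trajectory`.
#' @export
ankle_trajectory <- function(points, label = c("A", "B", "C", "PM"),
                             movement = c("plantar_dorsiflexion",
                                          "inversion_eversion")) {
  label <- match.arg(label)
  movement <- match.arg(movement)
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 3L || !all(is.finite(points))) {
    abort_ankle("`points` must be a finite n x 3 matrix with n >= 3",
                "invalid_parameter")
  }
  structure(list(points = points, label = label, movement = movement),
            class = "ankle_trajectory")
}

check_noncollinear <- function(pts) {
  ctr <- sweep(pts, 2L, colMeans(pts))
  sv <- svd(ctr, nu = 0L, nv = 0L)$d
  if (length(sv) < 2L || sv[2L] < 1e-9 * max(sv[1L], 1)) {
    abort_ankle("points are (numerically) collinear", "degenerate_geometry")
  }
  invisible(sv)
}

#' Least-squares plane through 3D points
#'
#' Fits `z = a x + b y + d` in least squares (design matrix `[x y 1]`) and
#' returns the normalized normal `(a, b, -1)/s` and offset `d/s`, so the
#' plane is `normal . p + offset = 0`. When the design matrix is
#' ill-conditioned (near-vertical planes) the fit falls back to total
#' (orthogonal) regression via the SVD of the centred points.
#'
#' @param points n x 3 matrix (cm), n >= 3, not all collinear.
#' @return A list with `normal` (unit 3-vector), `offset` (cm) and `method`
#'   (`"lsq"` or `"orthogonal"`).
#' @export
fit_plane <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3L) {
    abort_ankle("plane fitting needs at least 3 points", "invalid_parameter")
  }
  check_noncollinear(pts)
  A <- cbind(pts[, 1L], pts[, 2L], 1)
  qrA <- qr(A)
  use_fallback <- qrA$rank < 3L
  if (!use_fallback) {
    Rd <- abs(diag(qr.R(qrA)))
    use_fallback <- min(Rd) < 1e-8 * max(Rd)
  }
  if (!use_fallback) {
    coef <- qr.coef(qrA, pts[, 3L])
    nf <- c(coef[1L], coef[2L], -1)
    s <- norm3(nf)
    # steep planes break the z-parameterization: the regression noise is
    # amplified by 1/|n_z|, so hand planes tilted past ~60 degrees to the
    # total-least-squares fit
    if (!all(is.finite(nf)) || abs(nf[3L] / s) < 0.5) use_fallback <- TRUE
  }
  if (use_fallback) {
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2L, ctr))
    n <- sv$v[, 3L]
    return(list(normal = n, offset = -sum(n * ctr), method = "orthogonal"))
  }
  list(normal = nf / s, offset = coef[3L] / s, method = "lsq")
}

#' Rotate points so a plane normal becomes the z axis
#'
#' Rodrigues rotation about `v = normal x z` by `acos(normal . z)`; the
#' antiparallel case uses a fixed 180-degree rotation about x. Pairwise
#' distances are preserved exactly (the map is a rotation about the origin).
#'
#' @param points n x 3 matrix (cm).
#' @param normal Unit 3-vector.
#' @return A list with `points` (rotated n x 3 matrix) and `rotation` (3x3
#'   matrix `R` with `R %*% normal = z`).
#' @export
rotate_to_xy <- function(points, normal) {
  normal <- check_unit_axis(normal)
  nz <- clamp(normal[3L], -1, 1)
  if (nz > 1 - 1e-12) {
    R <- diag(3L)
  } else if (nz < -1 + 1e-12) {
    R <- rot_axis("x", pi)
  } else {
    v <- unit3(cross3(normal, c(0, 0, 1)))
    R <- rodrigues_rotation(v, acos(nz))
  }
  list(points = as.matrix(points) %*% t(R), rotation = R)
}

#' Algebraic least-squares circle fit in the plane
#'
#' Solves the linearized circle equation `c0 x + c1 y + c2 = x^2 + y^2` in
#' least squares; centre `(c0/2, c1/2)`, radius
#' `sqrt(c2 + xc^2 + yc^2)`.
#'
#' @param points_xy n x 2 matrix (cm), n >= 3, not collinear.
#' @return A list with `center` (2-vector) and `radius`.
#' @export
fit_circle_2d <- function(points_xy) {
  pts <- as.matrix(points_xy)
  if (ncol(pts) != 2L || nrow(pts) < 3L) {
    abort_ankle("circle fitting needs an n x 2 matrix with n >= 3",
                "invalid_parameter")
  }
  check_noncollinear(cbind(pts, 0))
  A <- cbind(pts[, 1L], pts[, 2L], 1)
  b <- pts[, 1L]^2 + pts[, 2L]^2
  coef <- qr.coef(qr(A), b)
  if (anyNA(coef)) {
    abort_ankle("degenerate circle fit (rank-deficient system)",
                "degenerate_geometry")
  }
  xc <- coef[1L] / 2
  yc <- coef[2L] / 2
  r2 <- coef[3L] + xc^2 + yc^2
  if (r2 <= 0) {
    abort_ankle("degenerate circle fit (non-positive squared radius)",
                "degenerate_fit")
  }
  list(center = c(xc, yc), radius = sqrt(r2))
}

arc_span_deg <- function(xy, center) {
  ang <- atan2(xy[, 2L] - center[2L], xy[, 1L] - center[1L])
  ang <- sort(ang)
  gaps <- diff(c(ang, ang[1L] + 2 * pi))
  rad2deg(2 * pi - max(gaps))
}

#' Circle fit to a 3D trajectory
#'
#' Plane fit, rotation of the points onto a horizontal plane, in-plane
#' algebraic circle fit, and rotation of the centre back to the original
#' plane. The circle normal is the fitted plane normal. Fits on arcs
#' spanning less than `min_arc_deg` emit a conditioning warning.
#'
#' @param traj An [ankle_trajectory()] or an n x 3 matrix of points.
#' @param min_arc_deg Arc-extent guard in degrees.
#' @param normal Optional externally supplied plane normal (e.g. a shared
#'   movement-group normal); when given, the per-trajectory plane fit is
#'   skipped.
#' @return An object of class `ankle_circle_fit` with `center` (3-vector,
#'   cm), `normal` (unit 3-vector), `radius` (cm), `rms_residual` (cm),
#'   `arc_deg`, `n_points`, and the source `label`/`movement` when fitted
#'   from a trajectory.
#' @export
fit_circle_3d <- function(traj, min_arc_deg = 5, normal = NULL) {
  label <- movement <- NA_character_
  if (inherits(traj, "ankle_trajectory")) {
    pts <- traj$points
    label <- traj$label
    movement <- traj$movement
  } else {
    pts <- as.matrix(traj)
  }
  pf <- if (is.null(normal)) fit_plane(pts) else list(normal = check_unit_axis(normal))
  rot <- rotate_to_xy(pts, pf$normal)
  c2 <- fit_circle_2d(rot$points[, 1:2, drop = FALSE])
  z0 <- mean(rot$points[, 3L])
  center <- drop(t(rot$rotation) %*% c(c2$center, z0))
  rms <- sqrt(mean((dist_to_point(pts, center) - c2$radius)^2))
  span <- arc_span_deg(rot$points[, 1:2, drop = FALSE], c2$center)
  if (span < min_arc_deg) {
    warning(sprintf("circle fit on a short arc (%.2f deg): poorly conditioned",
                    span), call. = FALSE)
  }
  structure(list(center = center, normal = pf$normal, radius = c2$radius,
                 rms_residual = rms, arc_deg = span, n_points = nrow(pts),
                 label = label, movement = movement),
            class = "ankle_circle_fit")
}

#' @export
print.ankle_circle_fit <- function(x, ...) {
  cat(sprintf("3D circle fit (%s%s): center (%.4f, %.4f, %.4f) cm, r = %.4f cm\n",
              ifelse(is.na(x$label), "points", x$label),
              ifelse(is.na(x$movement), "", paste0(", ", x$movement)),
              x$center[1], x$center[2], x$center[3], x$radius))
  cat(sprintf("  normal (%.4f, %.4f, %.4f), rms residual %.3g cm, arc %.1f deg\n",
              x$normal[1], x$normal[2], x$normal[3], x$rms_residual, x$arc_deg))
  invisible(x)
}

#' Aggregate circle fits into a single axis centre and direction
#'
#' Sign-aligns the circle normals to a common hemisphere (flipping any normal
#' opposing the first, then flipping all so the aggregated normal has
#' non-positive y, the mediolateral sign convention), and takes the
#' componentwise median of centres and normals; the median normal is
#' re-normalized.
#'
#' @param circles Non-empty list of `ankle_circle_fit` objects.
#' @return A list with `center` (3-vector) and `normal` (unit 3-vector).
#' @export
aggregate_axis <- function(circles) {
  if (length(circles) == 0L) {
    abort_ankle("`circles` must contain at least one circle fit",
                "invalid_parameter")
  }
  normals <- t(vapply(circles, `[[`, numeric(3L), "normal"))
  centers <- t(vapply(circles, `[[`, numeric(3L), "center"))
  ref <- normals[1L, ]
  for (i in seq_len(nrow(normals))) {
    if (sum(normals[i, ] * ref) < 0) normals[i, ] <- -normals[i, ]
  }
  med_n <- apply(normals, 2L, stats::median)
  if (med_n[2L] > 1e-9) {
    normals <- -normals
    med_n <- -med_n
  }
  nn <- norm3(med_n)
  if (nn < 1e-9) {
    abort_ankle("aggregated normal vanished (inconsistent circle normals)",
                "degenerate_geometry")
  }
  list(center = apply(centers, 2L, stats::median), normal = med_n / nn)
}

#' Intersect an axis with the sagittal plane
#'
#' Parametric line `center + d * direction` meets y = 0 at
#' `d = -center_y / direction_y`; the returned point has its y component set
#' to exactly zero.
#'
#' @param center 3-vector on the axis (cm).
#' @param direction Axis direction 3-vector (non-zero y component).
#' @return 3-vector with `[2] == 0`.
#' @export
sagittal_intersection <- function(center, direction) {
  center <- as_vec3(center, "center")
  direction <- as_vec3(direction, "direction")
  if (abs(direction[2L]) < 1e-12) {
    abort_ankle("axis is parallel to the sagittal plane: no intersection",
                "no_intersection")
  }
  d <- -center[2L] / direction[2L]
  r <- center + d * direction
  r[2L] <- 0
  r
}

#' Pluecker line coordinates of an axis
#'
#' Six-vector `[omega : m]` with moment `m = r x omega`; satisfies the line
#' constraint `omega . m = 0`.
#'
#' @param point_r 3-vector on the line (cm).
#' @param direction Line direction; normalized (with a warning) if not unit.
#' @return Named 6-vector `(wx, wy, wz, mx, my, mz)`.
#' @export
plucker_coords <- function(point_r, direction) {
  r <- as_vec3(point_r, "point_r")
  w <- as_vec3(direction, "direction")
  if (abs(norm3(w) - 1) > 1e-9) {
    warning("`direction` is not unit length: normalizing", call. = FALSE)
    w <- unit3(w, "direction")
  }
  m <- cross3(r, w)
  c(wx = w[1L], wy = w[2L], wz = w[3L], mx = m[1L], my = m[2L], mz = m[3L])
}

axis_estimate <- function(circles) {
  agg <- aggregate_axis(circles)
  r <- sagittal_intersection(agg$center, agg$normal)
  structure(list(point_r = r, direction = agg$normal,
                 plucker = plucker_coords(r, agg$normal),
                 median_center = agg$center, circles = circles),
            class = "ankle_axis")
}

#' @export
print.ankle_axis <- function(x, ...) {
  cat(sprintf("Axis estimate: r = (%.4f, %.4f, %.4f) cm, omega = (%.4f, %.4f, %.4f)\n",
              x$point_r[1], x$point_r[2], x$point_r[3],
              x$direction[1], x$direction[2], x$direction[3]))
  cat(sprintf("  Pluecker [%s]\n",
              paste(sprintf("%.4g", x$plucker), collapse = ": ")))
  invisible(x)
}

#' Shared plane normal of a trajectory group
#'
#' Trajectories produced by rotation about one fixed axis lie in parallel
#' planes; their common normal is estimated jointly as the direction
#' minimizing the total squared out-of-plane deviation of all trajectories
#' at once (third right singular vector of the stacked per-trajectory
#' centred points). Large-radius trajectories carry most of the signal and
#' stabilize the estimate for trajectories that pass close to the axis.
#'
#' @param trajectories List of [ankle_trajectory()] objects (or n x 3
#'   matrices).
#' @return Unit 3-vector.
#' @export
group_plane_normal <- function(trajectories) {
  stacked <- do.call(rbind, lapply(trajectories, function(tr) {
    pts <- if (inherits(tr, "ankle_trajectory")) tr$points else as.matrix(tr)
    sweep(pts, 2L, colMeans(pts))
  }))
  check_noncollinear(stacked)
  svd(stacked)$v[, 3L]
}

#' Estimate the TC and ST axes from grouped trajectories
#'
#' Fits a 3D circle to every trajectory, aggregates per movement group
#' (median centre and sign-aligned median normal), intersects each
#' aggregated axis with the sagittal plane and packs Pluecker coordinates.
#' The plantar/dorsiflexion group yields the talocrural axis, the
#' inversion/eversion group the subtalar axis. By default all trajectories
#' of one movement share one jointly fitted plane direction
#' ([group_plane_normal()]); per-trajectory plane fits are available with
#' `shared_normal = FALSE`.
#'
#' @param trajectories List of [ankle_trajectory()] objects, or a data.frame
#'   with columns `label`, `movement`, `x`, `y`, `z` (and optionally `t`).
#' @param min_arc_deg Arc guard passed to [fit_circle_3d()].
#' @param shared_normal Fit one common plane direction per movement group.
#' @return A list with `tc` and `st` (`ankle_axis` or `NULL` when the group
#'   is missing) and `partial` (TRUE when a movement group is absent).
#' @export
estimate_axes <- function(trajectories, min_arc_deg = 5,
                          shared_normal = TRUE) {
  if (is.data.frame(trajectories)) {
    trajectories <- trajectories_from_frame(trajectories)
  }
  mv <- vapply(trajectories, `[[`, character(1L), "movement")
  groups <- split(trajectories, mv)
  fit_group <- function(g) {
    nrm <- if (shared_normal) group_plane_normal(g)
    axis_estimate(lapply(g, fit_circle_3d, min_arc_deg = min_arc_deg,
                         normal = nrm))
  }
  tc <- if (!is.null(groups$plantar_dorsiflexion)) {
    fit_group(groups$plantar_dorsiflexion)
  }
  st <- if (!is.null(groups$inversion_eversion)) {
    fit_group(groups$inversion_eversion)
  }
  list(tc = tc, st = st, partial = is.null(tc) || is.null(st))
}

trajectories_from_frame <- function(df) {
  need <- c("label", "movement", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort_ankle(sprintf("trajectory data must have columns %s",
                        paste(need, collapse = ", ")),
                "schema")
  }
  parts <- split(df, list(df$label, df$movement), drop = TRUE)
  lapply(unname(parts), function(p) {
    ankle_trajectory(as.matrix(p[, c("x", "y", "z")]),
                     label = as.character(p$label[1L]),
                     movement = as.character(p$movement[1L]))
  })
}
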