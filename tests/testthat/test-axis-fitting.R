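# helper: exact circle in 3D from centre, radius, orthonormal in-plane frame
make_circle <- function(center, normal, radius, angles) {
  normal <- normal / sqrt(sum(normal^2))
  seed <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- anklekin:::cross3(normal, seed)
  u <- u / sqrt(sum(u^2))
  v <- anklekin:::cross3(normal, u)
  t(vapply(angles, function(a) {
    center + radius * (cos(a) * u + sin(a) * v)
  }, numeric(3)))
}

test_that("plane fitting recovers exact and noisy planes", {
  set.seed(17)
  xy <- cbind(runif(30, -5, 5), runif(30, -5, 5))
  flat <- fit_plane(cbind(xy, 0))
  expect_equal(abs(flat$normal[3]), 1, tolerance = 1e-12)
  expect_equal(flat$offset, 0, tolerance = 1e-12)
  # algebraic identity: z = 2x + 3y + 1 has normal prop to (2, 3, -1)
  pl <- fit_plane(cbind(xy, 2 * xy[, 1] + 3 * xy[, 2] + 1))
  s <- sqrt(sum(c(2, 3, -1)^2))
  expect_vec_equal(pl$normal * sign(pl$normal[1]), c(2, 3, -1) / s, 1e-9)
  expect_equal(pl$offset * sign(pl$normal[1]), 1 / s, tolerance = 1e-9)
  # noisy plane: normal within 1 degree
  noisy <- cbind(xy, 0.5 * xy[, 1] - 0.2 * xy[, 2] + rnorm(30, sd = 0.01))
  pn <- fit_plane(noisy)
  expect_lt(dir_angle(pn$normal, c(0.5, -0.2, -1)), 1 * pi / 180)
  # near-vertical plane engages the orthogonal fallback and still works
  vert <- cbind(rep(2, 30) + rnorm(30, sd = 1e-9), runif(30, -5, 5),
                runif(30, -5, 5))
  pv <- fit_plane(vert)
  expect_lt(dir_angle(pv$normal, c(1, 0, 0)), 1e-3)
  expect_error(fit_plane(cbind(1:5, 1:5, 1:5)),
               class = "anklekin_degenerate_geometry")
})

test_that("rotation onto the horizontal plane is an isometry sending n to z", {
  set.seed(18)
  pts <- matrix(rnorm(60), 20, 3)
  idn <- rotate_to_xy(pts, c(0, 0, 1))
  expect_equal(idn$points, pts)
  rx <- rotate_to_xy(pts, c(1, 0, 0))
  expect_vec_equal(drop(rx$rotation %*% c(1, 0, 0)), c(0, 0, 1), 1e-12)
  anti <- rotate_to_xy(pts, c(0, 0, -1))
  expect_vec_equal(drop(anti$rotation %*% c(0, 0, -1)), c(0, 0, 1), 1e-12)
  for (i in 1:5) {
    n <- random_unit()
    rot <- rotate_to_xy(pts, n)
    expect_vec_equal(drop(rot$rotation %*% n), c(0, 0, 1), 1e-9)
    expect_vec_equal(as.matrix(dist(rot$points)), as.matrix(dist(pts)), 1e-12)
  }
})

test_that("planar circle fit solves the linearized system exactly", {
  three <- fit_circle_2d(rbind(c(1, 0), c(0, 1), c(-1, 0)))
  expect_vec_equal(three$center, c(0, 0), 1e-12)
  expect_equal(three$radius, 1, tolerance = 1e-12)
  a <- seq(0, 2 * pi, length.out = 51)[-51]
  exact <- fit_circle_2d(cbind(2 + 5 * cos(a), 3 + 5 * sin(a)))
  expect_vec_equal(exact$center, c(2, 3), 1e-9)
  expect_equal(exact$radius, 5, tolerance = 1e-9)
  # short noisy arc: radius bias stays bounded (seeded regression)
  set.seed(19)
  arc <- seq(0, 20 * pi / 180, length.out = 40)
  noisy <- cbind(10 * cos(arc), 10 * sin(arc)) + matrix(rnorm(80, sd = 0.01), 40, 2)
  short <- fit_circle_2d(noisy)
  expect_lt(abs(short$radius - 10), 1.5)
  expect_error(fit_circle_2d(cbind(1:5, 2 * (1:5))),
               class = "anklekin_degenerate_geometry")
})

test_that("3D circle fit recovers tilted circles and is rigid-motion equivariant", {
  a <- seq(0.2, 2 * pi, length.out = 40)
  flat <- make_circle(c(1, -2, 0), c(0, 0, 1), 4, a)
  f3 <- fit_circle_3d(flat)
  f2 <- fit_circle_2d(flat[, 1:2])
  expect_vec_equal(f3$center[1:2], f2$center, 1e-9)
  expect_equal(f3$radius, f2$radius, tolerance = 1e-9)
  # 30-degree tilted plane, radius 7
  n30 <- c(sin(pi / 6), 0, cos(pi / 6))
  tilted <- make_circle(c(2, 1, -3), n30, 7, a)
  ft <- fit_circle_3d(tilted)
  expect_vec_equal(ft$center, c(2, 1, -3), 1e-9)
  expect_equal(ft$radius, 7, tolerance = 1e-9)
  expect_lt(dir_angle(ft$normal, n30), 1e-9)
  expect_lt(ft$rms_residual, 1e-9)
  # equivariance under random rigid motions
  set.seed(20)
  for (i in 1:5) {
    R <- random_rotation(); tr <- rnorm(3, sd = 4)
    moved <- sweep(tilted %*% t(R), 2, tr, "+")
    fm <- fit_circle_3d(moved)
    expect_vec_equal(fm$center, drop(R %*% ft$center) + tr, 1e-9)
    expect_equal(fm$radius, ft$radius, tolerance = 1e-9)
    expect_lt(dir_angle(fm$normal, drop(R %*% ft$normal)), 1e-7)
  }
  # circles of random orientation and radius leave zero residual
  for (i in 1:5) {
    circ <- make_circle(rnorm(3, sd = 5), random_unit(), runif(1, 0.5, 20), a)
    expect_lt(fit_circle_3d(circ)$rms_residual, 1e-9)
  }
})

test_that("short arcs trigger the conditioning warning", {
  a <- seq(0, 3 * pi / 180, length.out = 20)
  arc <- make_circle(c(0, 0, 0), c(0, 0, 1), 10, a)
  expect_warning(fit_circle_3d(arc), "short arc")
})

test_that("single-axis motion produces circles whose normal is the joint axis", {
  m <- default_model
  thetas <- seq(-15, 15, length.out = 30) * pi / 180
  traj_tc <- t(vapply(thetas, function(t1) {
    forward_kinematics(m, t1, 0, m$points$A0)
  }, numeric(3)))
  f <- fit_circle_3d(traj_tc)
  expect_lt(dir_angle(f$normal, m$twist_tc$omega), 1e-6)
  traj_st <- t(vapply(thetas, function(t2) {
    forward_kinematics(m, 0, t2, m$points$B0)
  }, numeric(3)))
  fs <- fit_circle_3d(traj_st)
  expect_lt(dir_angle(fs$normal, m$twist_st$omega), 1e-6)
})

test_that("axis aggregation takes sign-aligned medians", {
  a <- seq(0.1, 2 * pi, length.out = 25)
  c1 <- fit_circle_3d(make_circle(c(0, 1, 0), c(0, -1, 0.2), 5, a))
  expect_lt(dir_angle(aggregate_axis(list(c1))$normal, c1$normal), 1e-12)
  expect_equal(aggregate_axis(list(c1))$center, c1$center)
  c2 <- c1; c2$normal <- -c1$normal
  agg <- aggregate_axis(list(c1, c2, c1))
  expect_lt(dir_angle(agg$normal, c1$normal), 1e-12)
  # convention: aggregated normal points to non-positive y
  expect_lte(agg$normal[2], 0)
  expect_error(aggregate_axis(list()), class = "anklekin_invalid_parameter")
})

test_that("sagittal intersection and Pluecker packing satisfy the line constraint", {
  r <- sagittal_intersection(c(1, 2, 3), c(0, 1, 0))
  expect_equal(r, c(1, 0, 3))
  expect_identical(r[2], 0)
  expect_equal(sagittal_intersection(c(4, 0, -1), c(0.3, 0.5, 0.2)),
               c(4, 0, -1))
  expect_error(sagittal_intersection(c(1, 2, 3), c(1, 0, 0)),
               class = "anklekin_no_intersection")
  # moment of a point on the axis: m = r x w, orthogonal to w
  set.seed(21)
  for (i in 1:10) {
    w <- random_unit(); r <- rnorm(3, sd = 5)
    pl <- plucker_coords(r, w)
    expect_lt(abs(sum(pl[1:3] * pl[4:6])), 1e-6)
  }
  expect_vec_equal(plucker_coords(2 * c(0.6, 0, 0.8), c(0.6, 0, 0.8))[4:6],
                   c(0, 0, 0), 1e-12)
  expect_warning(plucker_coords(c(1, 0, 0), c(0, 2, 0)), "normalizing")
})

test_that("published circle-fit summaries reproduce the printed axis rows", {
  fits <- reference_circle_fits()
  # inversion/eversion group: sagittal point (-0.174, 0, -5.43),
  # moment (-1.52, 4.17, 0.0487)
  agg_ie <- aggregate_axis(fits$inversion_eversion)
  expect_vec_equal(agg_ie$center, c(1.92, 0.783, -7.10), 0.005)
  r_ie <- sagittal_intersection(agg_ie$center, agg_ie$normal)
  expect_vec_equal(r_ie, c(-0.174, 0, -5.43), 0.02)
  pl_ie <- plucker_coords(r_ie, agg_ie$normal)
  expect_vec_equal(pl_ie[4:6], c(-1.52, 4.17, 0.0487), 0.02)
  # plantar/dorsiflexion group: (-0.0562, 0, -6.08) / (-5.78, 0.559, 0.0534)
  agg_pd <- aggregate_axis(fits$plantar_dorsiflexion)
  expect_vec_equal(agg_pd$center, c(0.121, 1.89, -6.70), 0.005)
  r_pd <- sagittal_intersection(agg_pd$center, agg_pd$normal)
  expect_vec_equal(r_pd, c(-0.0562, 0, -6.08), 0.02)
  pl_pd <- plucker_coords(r_pd, agg_pd$normal)
  expect_vec_equal(pl_pd[4:6], c(-5.78, 0.559, 0.0534), 0.03)
})

test_that("grouped estimation recovers both generating axes", {
  m <- default_model
  thetas <- seq(-15, 15, length.out = 25) * pi / 180
  trajs <- list()
  for (lab in c("A", "B", "C", "PM")) {
    p0 <- m$points[[if (lab == "PM") "PM" else paste0(lab, "0")]]
    trajs[[length(trajs) + 1]] <- ankle_trajectory(
      t(vapply(thetas, function(t1) forward_kinematics(m, t1, 0, p0),
               numeric(3))), label = lab, movement = "plantar_dorsiflexion")
    trajs[[length(trajs) + 1]] <- ankle_trajectory(
      t(vapply(thetas, function(t2) forward_kinematics(m, 0, t2, p0),
               numeric(3))), label = lab, movement = "inversion_eversion")
  }
  est <- estimate_axes(trajs)
  expect_false(est$partial)
  expect_lt(dir_angle(est$tc$direction, default_ref$omega_tc), 1e-6)
  expect_lt(dir_angle(est$st$direction, default_ref$omega_st), 1e-6)
  expect_vec_equal(est$tc$point_r, default_ref$r1, 1e-6)
  expect_vec_equal(est$st$point_r, default_ref$r2, 1e-6)
  # Pluecker constraint on computed estimates
  expect_lt(abs(sum(est$tc$plucker[1:3] * est$tc$plucker[4:6])), 1e-6)
  expect_lt(abs(sum(est$st$plucker[1:3] * est$st$plucker[4:6])), 1e-6)
  # a single trajectory per group is its own axis
  one <- estimate_axes(trajs[1])
  expect_true(one$partial)
  cf <- fit_circle_3d(trajs[[1]])
  expect_lt(dir_angle(one$tc$direction, cf$normal), 1e-9)
})

test_that("a shared group normal equals the common plane of exact parallel circles", {
  a <- seq(0.15, 2 * pi, length.out = 30)
  n <- c(0.2, -0.9, 0.4); n <- n / sqrt(sum(n^2))
  trs <- lapply(1:3, function(i) {
    make_circle(rnorm(3, sd = 3), n, runif(1, 2, 8), a)
  })
  expect_lt(dir_angle(group_plane_normal(trs), n), 1e-9)
})
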