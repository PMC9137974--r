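test_that("tetrahedron apex solves closed forms and round-trips random apexes", {
  # regular tetrahedron over an equilateral base of side 1: height sqrt(2/3)
  base <- list(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  apex <- apex_from_base(base[[1]], base[[2]], base[[3]], 1, 1, 1, sign = 1)
  expect_equal(apex[3], sqrt(2 / 3), tolerance = 1e-12)
  ctd <- Reduce(`+`, base) / 3
  expect_vec_equal(apex[1:2], ctd[1:2], 1e-12)
  # coplanar apex: zero out-of-plane component
  flat <- c(2, 0.3, 0)
  lf <- vapply(base, function(p) sqrt(sum((p - flat)^2)), 0)
  sol <- apex_from_base(base[[1]], base[[2]], base[[3]], lf[1], lf[2], lf[3])
  expect_vec_equal(sol, flat, 1e-6)
  # forward-distance oracle round trip, 1000 random apexes over random bases
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    p1 <- rnorm(3, sd = 5); p2 <- rnorm(3, sd = 5); p3 <- rnorm(3, sd = 5)
    n <- anklekin:::cross3(p2 - p1, p3 - p1)
    if (sqrt(sum(n^2)) < 1) next
    true <- rnorm(3, sd = 5)
    l <- c(sqrt(sum((true - p1)^2)), sqrt(sum((true - p2)^2)),
           sqrt(sum((true - p3)^2)))
    side <- sign(sum((true - p1) * n))
    if (side == 0) side <- 1
    got <- apex_from_base(p1, p2, p3, l[1], l[2], l[3], sign = side)
    worst <- max(worst, max(abs(got - true)))
  }
  expect_lt(worst, 1e-9)
})

test_that("apex solving is consistent under base relabeling", {
  set.seed(12)
  p <- lapply(1:3, function(i) rnorm(3, sd = 4))
  true <- rnorm(3, sd = 4)
  l <- vapply(p, function(pi) sqrt(sum((pi - true)^2)), 0)
  n <- anklekin:::cross3(p[[2]] - p[[1]], p[[3]] - p[[1]])
  base_side <- sign(sum((true - p[[1]]) * n))
  for (perm in list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))) {
    np <- anklekin:::cross3(p[[perm[2]]] - p[[perm[1]]],
                            p[[perm[3]]] - p[[perm[1]]])
    s <- sign(sum((true - p[[perm[1]]]) * np))
    got <- apex_from_base(p[[perm[1]]], p[[perm[2]]], p[[perm[3]]],
                          l[perm[1]], l[perm[2]], l[perm[3]], sign = s)
    expect_vec_equal(got, true, 1e-9)
  }
})

test_that("impossible or degenerate tetrahedra raise classed errors", {
  err <- tryCatch(
    apex_from_base(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 10, 0.1, 0.1),
    anklekin_no_real_apex = function(e) e
  )
  expect_s3_class(err, "anklekin_no_real_apex")
  expect_true(is.numeric(err$radicand) && err$radicand < 0)
  expect_error(apex_from_base(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 1, 1, 1),
               class = "anklekin_degenerate_base")
  expect_error(apex_from_base(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), -1, 1, 1),
               class = "anklekin_invalid_parameter")
})

test_that("plane tilt returns the triangle normal and its angle to vertical", {
  out <- plane_tilt(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(out$alpha, 0, tolerance = 1e-12)
  vert <- plane_tilt(c(0, 0, 0), c(1, 0, 0), c(0.3, 0, 2))
  expect_equal(vert$alpha, pi / 2, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:5) {
    tri <- lapply(1:3, function(k) rnorm(3))
    out <- plane_tilt(tri[[1]], tri[[2]], tri[[3]])
    expect_lt(abs(sum(out$normal * (tri[[1]] - tri[[3]]))), 1e-12)
    expect_lt(abs(sum(out$normal * (tri[[2]] - tri[[3]]))), 1e-12)
    expect_equal(sqrt(sum(out$normal^2)), 1, tolerance = 1e-12)
  }
  expect_error(plane_tilt(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               class = "anklekin_degenerate_geometry")
})

test_that("tilted tetrahedron apexes reproduce the forward model", {
  # flat base: must agree with the direct construction
  b1 <- c(0, 0, 0); b3 <- c(2, 0, 0); ap <- c(1, 2, 0)
  true <- c(0.8, 0.7, -1.4)
  l <- c(sqrt(sum((true - b1)^2)), sqrt(sum((true - b3)^2)),
         sqrt(sum((true - ap)^2)))
  cand <- rotated_tetrahedron_apex(b1, b3, ap, l[1], l[2], l[3])
  expect_lt(min(anklekin:::dist_to_point(cand, true)), 1e-9)
  # synthetic platform poses: solve B from A plus two wire lengths
  m <- default_model; g <- default_geom
  set.seed(14)
  for (i in 1:50) {
    th <- runif(2, -15, 15) * pi / 180
    v <- fk_vertices(m, th[1], th[2])
    l <- wire_lengths(g, v)
    got <- rotated_tetrahedron_apex(g$anchors$B1, g$anchors$B3, v[1, ],
                                    l["lB1"], l["lB3"], g$edges[["dAB"]],
                                    ref_point = v[3, ],
                                    expected_edge = g$edges[["dBC"]],
                                    edge_tol = 1e-6)
    expect_vec_equal(got, v[2, ], 1e-9)
  }
  # expected edge perturbed to reject both candidates
  th <- c(0.1, -0.1)
  v <- fk_vertices(m, th[1], th[2])
  l <- wire_lengths(g, v)
  expect_error(
    rotated_tetrahedron_apex(g$anchors$B1, g$anchors$B3, v[1, ],
                             l["lB1"], l["lB3"], g$edges[["dAB"]],
                             ref_point = v[3, ],
                             expected_edge = g$edges[["dBC"]] + 5,
                             edge_tol = 1e-3),
    class = "anklekin_ambiguous_apex"
  )
})

test_that("rigid alignment recovers constructed transforms with det +1", {
  tri <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  id <- rigid_align(tri, tri)
  expect_vec_equal(id$R, diag(3), 1e-12)
  expect_vec_equal(id$p, c(0, 0, 0), 1e-12)
  Rz30 <- anklekin:::rot_axis("z", pi / 6)
  t0 <- c(0.4, -1.2, 2)
  moved <- sweep(tri %*% t(Rz30), 2, t0, "+")
  got <- rigid_align(tri, moved)
  expect_vec_equal(got$R, Rz30, 1e-9)
  expect_vec_equal(got$p, t0, 1e-9)
  # mirrored target: reflection branch rejected, rotation stays proper
  mir <- tri %*% diag(c(-1, 1, 1))
  gm <- rigid_align(tri, mir, congruence_tol = 10)
  expect_equal(det(gm$R), 1, tolerance = 1e-9)
  expect_error(rigid_align(tri, tri * 3), class = "anklekin_shape_mismatch")
})

test_that("solve_platform reproduces forward-model vertices exactly without noise", {
  m <- default_model; g <- default_geom
  v0 <- fk_vertices(m, 0, 0)
  sol0 <- solve_platform(g, wire_lengths(g, v0))
  expect_vec_equal(sol0$vertices, v0, 1e-9)
  expect_vec_equal(sol0$pose$R, diag(3), 1e-9)
  expect_lt(max(abs(sol0$residuals)), 1e-9)
  set.seed(15)
  worst <- 0
  for (i in 1:200) {
    th <- runif(2, -15, 15) * pi / 180
    v <- fk_vertices(m, th[1], th[2])
    sol <- solve_platform(g, wire_lengths(g, v))
    worst <- max(worst, max(abs(sol$vertices - v)))
    # the recovered pose maps the rest triangle onto the solved one
    expect_vec_equal(pose_apply(sol$pose, rbind(g$platform$A0, g$platform$B0,
                                                g$platform$C0)),
                     unname(sol$vertices), 1e-8)
  }
  expect_lt(worst, 1e-9)
  bad <- wire_lengths(g, v0); bad["lA1"] <- 1e6
  expect_error(solve_platform(g, bad), class = "anklekin_no_real_apex")
})

test_that("solved vertices degrade gracefully under Gaussian length noise", {
  m <- default_model; g <- default_geom
  sigma <- 0.05
  set.seed(16)
  verr <- numeric(0)
  edge_err <- numeric(0)
  n_ok <- 0
  for (i in 1:1000) {
    th <- runif(2, -15, 15) * pi / 180
    v <- fk_vertices(m, th[1], th[2])
    l <- wire_lengths(g, v) + rnorm(7, sd = sigma)
    sol <- tryCatch(solve_platform(g, l),
                    anklekin_ambiguous_apex = function(e) NULL)
    if (is.null(sol)) next
    n_ok <- n_ok + 1
    verr <- c(verr, sqrt(rowSums((sol$vertices - v)^2)))
    edge_err <- c(edge_err, abs(c(dist(sol$vertices)) - g$edges))
  }
  expect_gt(n_ok, 900)
  expect_lt(median(verr), 5 * sigma)
  # solved platform preserves the configured edges within 10x the noise
  expect_lt(max(edge_err), 10 * sigma)
})
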