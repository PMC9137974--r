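#' Draw-wire device geometry
#'
#' Anchor coordinates of the seven draw-wire sensors (three in module A, two
#' each in modules B and C), the rest-pose platform triangle and the module
#' radius. Platform edge lengths are derived from the platform triangle and
#' used as the known tetrahedron sides when solving modules B and C.
#'
#' @param anchors Named list of 3-vectors `A1`, `A2`, `A3`, `B1`, `B3`, `C1`,
#'   `C3` (cm, base frame).
#' @param platform Named list of rest-pose platform vertices `A0`, `B0`, `C0`.
#' @param rm Module radius in cm (non-negative).
#' @return An object of class `ankle_geometry`.
#' @export
device_geometry <- function(anchors, platform, rm = 0) {
  need <- c("A1", "A2", "A3", "B1", "B3", "C1", "C3")
  if (!all(need %in% names(anchors))) {
    abort_ankle(sprintf("`anchors` must contain %s", paste(need, collapse = ", ")),
                "invalid_parameter")
  }
  anchors <- lapply(anchors[need], as_vec3)
  platform <- lapply(platform[c("A0", "B0", "C0")], as_vec3)
  check_nonnegative(rm, "rm")
  # module-A base must span a plane
  n <- cross3(anchors$A2 - anchors$A1, anchors$A3 - anchors$A1)
  if (norm3(n) < 1e-9) {
    abort_ankle("module-A anchors are collinear", "degenerate_geometry")
  }
  edges <- c(dAB = norm3(platform$A0 - platform$B0),
             dBC = norm3(platform$B0 - platform$C0),
             dCA = norm3(platform$C0 - platform$A0))
  if (any(edges <= 0) ||
      edges["dAB"] + edges["dBC"] <= edges["dCA"] ||
      edges["dBC"] + edges["dCA"] <= edges["dAB"] ||
      edges["dCA"] + edges["dAB"] <= edges["dBC"]) {
    abort_ankle("platform edges violate the triangle inequality",
                "degenerate_geometry")
  }
  structure(list(anchors = anchors, platform = platform, edges = edges, rm = rm),
            class = "ankle_geometry")
}

#' Default device geometry for an ankle reference model
#'
#' Places the three sensor modules on a horizontal plate worn on the lower
#' shank, `anchor_height` above the platform plane, each module centred at
#' `anchor_radius` from the shank axis in the direction of its platform
#' vertex; module A carries three anchors spread on a circle of radius
#' `rm`, modules B and C carry two anchors each at the tangential extremes.
#' The defaults give rest-pose wire lengths of roughly 8-12 cm for an
#' average adult.
#'
#' @param ref An [ankle_reference()].
#' @param rm Module radius in cm.
#' @param anchor_radius Distance of module centres from the shank axis in cm
#'   (default `0.8 * ref$rp`).
#' @param anchor_height Height of the anchor plate above the platform plane
#'   in cm.
#' @return An `ankle_geometry`.
#' @export
default_device_geometry <- function(ref, rm = 4, anchor_radius = NULL,
                                    anchor_height = 10) {
  if (is.null(anchor_radius)) anchor_radius <- 0.8 * ref$rp
  check_positive(anchor_radius, "anchor_radius")
  check_positive(rm, "rm")
  check_positive(anchor_height, "anchor_height")
  z_anchor <- -ref$dm + anchor_height
  module <- function(angle_deg, local_deg) {
    a <- deg2rad(angle_deg)
    centre <- c(anchor_radius * cos(a), anchor_radius * sin(a), z_anchor)
    lapply(local_deg, function(phi) {
      centre + rm * c(cos(deg2rad(phi)), sin(deg2rad(phi)), 0)
    })
  }
  A <- module(0, c(90, 210, 330))
  B <- module(120, c(120 + 90, 120 - 90))
  C <- module(-120, c(-120 + 90, -120 - 90))
  device_geometry(
    anchors = list(A1 = A[[1L]], A2 = A[[2L]], A3 = A[[3L]],
                   B1 = B[[1L]], B3 = B[[2L]],
                   C1 = C[[1L]], C3 = C[[2L]]),
    platform = list(A0 = ref$A0, B0 = ref$B0, C0 = ref$C0),
    rm = rm
  )
}

#' @export
print.ankle_geometry <- function(x, ...) {
  cat("Draw-wire device geometry (7 sensors: A1-A3, B1, B3, C1, C3)\n")
  cat(sprintf("  module radius rm = %.2f cm\n", x$rm))
  cat(sprintf("  platform edges: dAB = %.3f, dBC = %.3f, dCA = %.3f cm\n",
              x$edges["dAB"], x$edges["dBC"], x$edges["dCA"]))
  invisible(x)
}

#' Wire lengths of a platform configuration
#'
#' Forward sensor model: the Euclidean distances from each anchor to its
#' platform vertex.
#'
#' @param geom An `ankle_geometry`.
#' @param vertices 3 x 3 matrix with rows A, B, C (cm), e.g. from
#'   [fk_vertices()].
#' @return Named numeric vector `lA1, lA2, lA3, lB1, lB3, lC1, lC3` (cm).
#' @export
wire_lengths <- function(geom, vertices) {
  an <- geom$anchors
  c(lA1 = norm3(vertices[1L, ] - an$A1),
    lA2 = norm3(vertices[1L, ] - an$A2),
    lA3 = norm3(vertices[1L, ] - an$A3),
    lB1 = norm3(vertices[2L, ] - an$B1),
    lB3 = norm3(vertices[2L, ] - an$B3),
    lC1 = norm3(vertices[3L, ] - an$C1),
    lC3 = norm3(vertices[3L, ] - an$C3))
}

#' Tetrahedron apex from three base points and three edge lengths
#'
#' Solves the trilateration tetrahedron analytically: in-base-plane
#' coordinates from the two-circle intersection construction expressed in a
#' local orthonormal frame, out-of-plane height as the square root of the
#' remaining radicand, with the caller-chosen side of the base plane.
#'
#' @param p1,p2,p3 Non-collinear base 3-vectors (cm).
#' @param l1,l2,l3 Positive apex distances to `p1`, `p2`, `p3` (cm).
#' @param sign `+1` or `-1`: side of the base plane (relative to the normal
#'   `cross(p2 - p1, p3 - p1)`) on which the apex lies.
#' @param tol Tolerance for a slightly negative radicand (numerical noise on
#'   consistent inputs), in cm^2.
#' @return Apex 3-vector (cm).
#' @export
apex_from_base <- function(p1, p2, p3, l1, l2, l3, sign = 1, tol = 1e-8) {
  p1 <- as_vec3(p1, "p1"); p2 <- as_vec3(p2, "p2"); p3 <- as_vec3(p3, "p3")
  for (l in list(l1 = l1, l2 = l2, l3 = l3)) {
    if (!is.finite(l) || l <= 0) {
      abort_ankle("edge lengths must be positive", "invalid_parameter")
    }
  }
  ex <- p2 - p1
  d <- norm3(ex)
  if (d < 1e-12) abort_ankle("base points p1, p2 coincide", "degenerate_base")
  ex <- ex / d
  u3 <- p3 - p1
  i <- sum(ex * u3)
  ey <- u3 - i * ex
  j <- norm3(ey)
  if (j < 1e-9) abort_ankle("base points are collinear", "degenerate_base")
  ey <- ey / j
  ez <- cross3(ex, ey)
  x <- (l1^2 - l2^2 + d^2) / (2 * d)
  y <- (l1^2 - l3^2 + i^2 + j^2 - 2 * i * x) / (2 * j)
  h2 <- l1^2 - x^2 - y^2
  if (h2 < -tol) {
    abort_ankle(sprintf("no real apex: inconsistent lengths (radicand %.3e cm^2)", h2),
                "no_real_apex", radicand = h2)
  }
  h <- sqrt(max(h2, 0))
  p1 + x * ex + y * ey + sign * h * ez
}

#' Tilt of a base triangle relative to the horizontal plane
#'
#' Unit normal of the triangle (from the two distinct edge vectors
#' `(B1 - Ap) x (B3 - Ap)`) and its angle to the z axis.
#'
#' @param B1,B3,Ap Non-collinear 3-vectors (cm).
#' @return List with `normal` (unit 3-vector) and `alpha` (radians, in
#'   `[0, pi]`).
#' @export
plane_tilt <- function(B1, B3, Ap) {
  B1 <- as_vec3(B1, "B1"); B3 <- as_vec3(B3, "B3"); Ap <- as_vec3(Ap, "Ap")
  n <- cross3(B1 - Ap, B3 - Ap)
  if (norm3(n) < 1e-9) {
    abort_ankle("base triangle is degenerate (collinear points)",
                "degenerate_geometry")
  }
  n <- n / norm3(n)
  list(normal = n, alpha = acos(clamp(n[3L], -1, 1)))
}

# rotation (about an axis through `origin`) that maps the plane with unit
# normal `n` onto a horizontal plane; identity when already horizontal.
flattening_rotation <- function(n, origin) {
  nz <- clamp(n[3L], -1, 1)
  if (abs(nz) > 1 - 1e-12) {
    return(list(R = diag(3L), origin = origin))
  }
  # align n with +z (or -z, whichever is nearer) so the rotation is minimal
  target_sign <- if (nz >= 0) 1 else -1
  axis <- unit3(cross3(n, c(0, 0, target_sign)))
  theta <- acos(clamp(target_sign * nz, -1, 1))
  list(R = rodrigues_rotation(axis, theta), origin = origin)
}

apply_about <- function(rot, p) drop(rot$R %*% (p - rot$origin)) + rot$origin
unapply_about <- function(rot, p) drop(t(rot$R) %*% (p - rot$origin)) + rot$origin

#' Apex of a tilted tetrahedron by rotation onto the horizontal plane
#'
#' Solves modules B and C: the base triangle (two module anchors plus the
#' previously solved apex) is rotated about an in-plane axis onto a
#' horizontal plane, the apex is found there with [apex_from_base()], and
#' both mirror candidates are rotated back. If `ref_point` and
#' `expected_edge` are supplied, the candidate whose distance to `ref_point`
#' matches `expected_edge` is returned (ties broken by the lower-z
#' candidate); otherwise both candidates are returned as a 2 x 3 matrix.
#'
#' @param b1,b3 Module anchor 3-vectors (cm).
#' @param apex_known Previously solved platform vertex (cm).
#' @param l1,l3 Wire lengths to `b1`, `b3` (cm).
#' @param d_apex Known platform edge from the sought vertex to `apex_known`
#'   (cm).
#' @param ref_point Optional disambiguation point (cm).
#' @param expected_edge Optional expected distance from the solved vertex to
#'   `ref_point` (cm).
#' @param edge_tol Acceptance tolerance on the expected edge (cm).
#' @return A 3-vector (when disambiguated) or a 2 x 3 matrix of candidates.
#' @export
rotated_tetrahedron_apex <- function(b1, b3, apex_known, l1, l3, d_apex,
                                     ref_point = NULL, expected_edge = NULL,
                                     edge_tol = 0.5) {
  b1 <- as_vec3(b1, "b1"); b3 <- as_vec3(b3, "b3")
  apex_known <- as_vec3(apex_known, "apex_known")
  tilt <- plane_tilt(b1, b3, apex_known)
  rot <- flattening_rotation(tilt$normal, b1)
  b3f <- apply_about(rot, b3)
  apf <- apply_about(rot, apex_known)
  cand <- lapply(c(1, -1), function(s) {
    unapply_about(rot, apex_from_base(b1, b3f, apf, l1, l3, d_apex, sign = s))
  })
  cand <- do.call(rbind, cand)
  if (is.null(ref_point) || is.null(expected_edge)) {
    return(cand)
  }
  ref_point <- as_vec3(ref_point, "ref_point")
  errs <- abs(dist_to_point(cand, ref_point) - expected_edge)
  if (min(errs) > edge_tol) {
    abort_ankle(sprintf("ambiguous apex: both mirror candidates miss the expected edge (best error %.4g cm)",
                        min(errs)),
                "ambiguous_apex", candidates = cand, errors = errs)
  }
  if (abs(errs[1L] - errs[2L]) < 1e-12) {
    return(cand[which.min(cand[, 3L]), ])
  }
  cand[which.min(errs), ]
}

#' Least-squares rigid alignment of two congruent triangles
#'
#' Proper rigid transform (rotation with determinant +1 plus translation)
#' minimizing the summed squared distance between corresponding points
#' (Kabsch / SVD construction); reflections are rejected by the determinant
#' constraint.
#'
#' @param reference,solved 3 x 3 matrices of corresponding points (rows).
#' @param congruence_tol Maximal allowed edge-length mismatch in cm.
#' @return An `ankle_pose` `g` with `pose_apply(g, reference) ~ solved`.
#' @export
rigid_align <- function(reference, solved, congruence_tol = 0.5) {
  X <- as.matrix(reference); Y <- as.matrix(solved)
  if (!all(dim(X) == c(3L, 3L)) || !all(dim(Y) == c(3L, 3L))) {
    abort_ankle("`reference` and `solved` must be 3 x 3 point matrices",
                "invalid_parameter")
  }
  edge <- function(M) c(norm3(M[1L, ] - M[2L, ]), norm3(M[2L, ] - M[3L, ]),
                        norm3(M[3L, ] - M[1L, ]))
  if (any(edge(X) < 1e-9) || any(edge(Y) < 1e-9)) {
    abort_ankle("degenerate triangle", "degenerate_geometry")
  }
  if (max(abs(edge(X) - edge(Y))) > congruence_tol) {
    abort_ankle(sprintf("triangles are not congruent (max edge mismatch %.4g cm)",
                        max(abs(edge(X) - edge(Y)))),
                "shape_mismatch")
  }
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- t(sweep(X, 2L, cx)) %*% sweep(Y, 2L, cy)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  new_pose(R, cy - drop(R %*% cx))
}

#' Solve the platform vertices and pose from seven wire lengths
#'
#' Analytic tetrahedral trilateration: the module-A vertex `Ap` is the apex
#' of the tetrahedron over the three A anchors (taken on the configured side
#' of the anchor plane); `Bp` and `Cp` are apexes of tilted tetrahedra over
#' (B1, B3, Ap) and (C1, C3, Ap) with the known platform edges as third
#' sides. Of the four mirror-candidate combinations the pair whose
#' separation best matches the platform edge `dBC` is kept. The platform
#' pose is the proper rigid transform aligning the rest-pose triangle onto
#' the solved one.
#'
#' @param geom An `ankle_geometry`.
#' @param lengths Named numeric vector with entries `lA1, lA2, lA3, lB1, lB3,
#'   lC1, lC3` (cm, all positive).
#' @param apex_side `"below"` (platform under the anchor plane, the default
#'   mounting) or `"above"`.
#' @param edge_tol Consistency tolerance on the `dBC` cross-check in cm.
#' @return An object of class `ankle_platform_solution`: `vertices` (3 x 3
#'   matrix A, B, C), `pose` (`ankle_pose`), `residuals` (per-sensor
#'   `|vertex - anchor| - length`, cm).
#' @export
solve_platform <- function(geom, lengths, apex_side = c("below", "above"),
                           edge_tol = 0.5) {
  apex_side <- match.arg(apex_side)
  need <- c("lA1", "lA2", "lA3", "lB1", "lB3", "lC1", "lC3")
  lengths <- unlist(lengths)[need]
  if (anyNA(lengths) || any(lengths <= 0)) {
    abort_ankle("`lengths` must contain positive lA1, lA2, lA3, lB1, lB3, lC1, lC3",
                "invalid_parameter")
  }
  an <- geom$anchors
  cand_A <- lapply(c(1, -1), function(s) {
    apex_from_base(an$A1, an$A2, an$A3,
                   lengths["lA1"], lengths["lA2"], lengths["lA3"], sign = s)
  })
  zs <- vapply(cand_A, `[`, numeric(1L), 3L)
  Ap <- if (apex_side == "below") cand_A[[which.min(zs)]] else cand_A[[which.max(zs)]]

  cand_B <- rotated_tetrahedron_apex(an$B1, an$B3, Ap,
                                     lengths["lB1"], lengths["lB3"],
                                     geom$edges[["dAB"]])
  cand_C <- rotated_tetrahedron_apex(an$C1, an$C3, Ap,
                                     lengths["lC1"], lengths["lC3"],
                                     geom$edges[["dCA"]])
  combos <- expand.grid(b = 1:2, c = 1:2)
  errs <- vapply(seq_len(nrow(combos)), function(k) {
    abs(norm3(cand_B[combos$b[k], ] - cand_C[combos$c[k], ]) -
          geom$edges[["dBC"]])
  }, numeric(1L))
  # physical plausibility filters before the dBC cross-check:
  # (a) the platform hangs on the chosen side of the anchor plate for the
  #     whole range of motion, so Bp/Cp candidates on the wrong side of the
  #     module-A base plane are rejected;
  # (b) the platform triangle cannot flip over, so the solved winding must
  #     match the rest-pose winding (mirror pairs reverse it)
  n_base <- cross3(an$A2 - an$A1, an$A3 - an$A1)
  if (sum(n_base * (Ap - an$A1)) < 0) n_base <- -n_base
  ok_side <- (drop((cand_B - matrix(an$A1, 2L, 3L, byrow = TRUE)) %*% n_base) > 0)
  ok_side <- outer(ok_side,
                   drop((cand_C - matrix(an$A1, 2L, 3L, byrow = TRUE)) %*% n_base) > 0,
                   "&")[cbind(combos$b, combos$c)]
  if (any(ok_side)) errs[!ok_side] <- Inf
  n_rest <- cross3(geom$platform$B0 - geom$platform$A0,
                   geom$platform$C0 - geom$platform$A0)
  ok_orient <- vapply(seq_len(nrow(combos)), function(k) {
    n_sol <- cross3(cand_B[combos$b[k], ] - Ap, cand_C[combos$c[k], ] - Ap)
    sum(n_sol * n_rest) > 0
  }, logical(1L))
  if (any(ok_orient & is.finite(errs))) errs[!ok_orient] <- Inf
  best <- which(errs <= min(errs) + 1e-12)
  if (length(best) > 1L) { # tie: prefer the lower-z pair (platform side)
    zsum <- vapply(best, function(k) {
      cand_B[combos$b[k], 3L] + cand_C[combos$c[k], 3L]
    }, numeric(1L))
    best <- best[which.min(zsum)]
  } else {
    best <- best[1L]
  }
  if (errs[best] > edge_tol) {
    abort_ankle(sprintf("platform edge cross-check failed at stage B/C selection (dBC error %.4g cm)",
                        errs[best]),
                "ambiguous_apex", errors = errs)
  }
  Bp <- cand_B[combos$b[best], ]
  Cp <- cand_C[combos$c[best], ]
  vertices <- rbind(A = Ap, B = Bp, C = Cp)
  colnames(vertices) <- c("x", "y", "z")

  ref_tri <- rbind(geom$platform$A0, geom$platform$B0, geom$platform$C0)
  pose <- rigid_align(ref_tri, vertices,
                      congruence_tol = max(edge_tol, 1e-6))
  anchor_of <- list(lA1 = an$A1, lA2 = an$A2, lA3 = an$A3,
                    lB1 = an$B1, lB3 = an$B3, lC1 = an$C1, lC3 = an$C3)
  vert_of <- c(lA1 = 1L, lA2 = 1L, lA3 = 1L, lB1 = 2L, lB3 = 2L,
               lC1 = 3L, lC3 = 3L)
  residuals <- vapply(need, function(nm) {
    norm3(vertices[vert_of[[nm]], ] - anchor_of[[nm]]) - lengths[[nm]]
  }, numeric(1L))
  structure(list(vertices = vertices, pose = pose, residuals = residuals),
            class = "ankle_platform_solution")
}

#' @export
print.ankle_platform_solution <- function(x, ...) {
  cat("Platform solution (cm):\n")
  print(round(x$vertices, 4))
  cat(sprintf("  max |residual| = %.3g cm\n", max(abs(x$residuals))))
  invisible(x)
}
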