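#' Anthropometric mean table for the ankle reference model
#'
#' Mean distances between the palpable malleolar landmarks and the points
#' defining the talocrural (TC) axis, plus the sagittal offset `Q` between the
#' TC and subtalar (ST) axis intersections and the ratio `Rratio = W/w` used
#' to place the TC sagittal intersection along the inter-malleolar segment.
#'
#' @param K,L,O,P,Q Lengths in cm (non-negative).
#' @param Rratio Dimensionless ratio W/w (positive).
#' @return An object of class `anthro_table`.
#' @examples
#' anthro_table()
#' @export
anthro_table <- function(K = 1.2, L = 1.1, O = 1.6, P = 1.0, Q = 0.5,
                         Rratio = 0.54) {
  for (nm in c("K", "L", "O", "P", "Q")) check_nonnegative(get(nm), nm)
  check_positive(Rratio, "Rratio")
  structure(list(K = K, L = L, O = O, P = P, Q = Q, Rratio = Rratio),
            class = "anthro_table")
}

#' @export
print.anthro_table <- function(x, ...) {
  cat("Anthropometric mean table (cm; Rratio dimensionless)\n")
  cat(sprintf("  K=%.2f L=%.2f O=%.2f P=%.2f Q=%.2f Rratio=%.2f\n",
              x$K, x$L, x$O, x$P, x$Q, x$Rratio))
  invisible(x)
}

#' Knee-to-ankle reference distance from body height
#'
#' The origin of the base frame sits between the knee and the ankle; the
#' distance from the origin down to the platform centre is proportional to
#' body height with the proportions of a standard body model: midway between
#' the knee-to-foot fraction (0.285) and the ankle-to-foot fraction (0.039),
#' which collapses to the coefficient 0.162.
#'
#' @param H Body height in cm (positive).
#' @param knee_foot_frac,ankle_foot_frac Body-model proportions.
#' @return Distance in cm.
#' @examples
#' knee_ankle_distance(175) # 28.35
#' @export
knee_ankle_distance <- function(H, knee_foot_frac = 0.285,
                                ankle_foot_frac = 0.039) {
  check_positive(H, "H")
  ((knee_foot_frac - ankle_foot_frac) / 2 + ankle_foot_frac) * H
}

#' Project the malleolar markers onto the sagittal plane
#'
#' Offsets the most medial point (MMP) by (P, ., O) and the most lateral point
#' (MLP) by (L, ., K) and drops both onto the sagittal plane y = 0, giving the
#' sagittal projections of the TC-axis defining points M1 and M2.
#'
#' @param MMP,MLP 3-vectors in cm (most medial / most lateral point).
#' @param table An [anthro_table()].
#' @return A list with 3-vectors `M1p` and `M2p` (both with y = 0).
#' @export
project_marker_points <- function(MMP, MLP, table = anthro_table()) {
  MMP <- as_vec3(MMP, "MMP")
  MLP <- as_vec3(MLP, "MLP")
  list(M1p = c(MMP[1L] - table$P, 0, MMP[3L] - table$O),
       M2p = c(MLP[1L] - table$L, 0, MLP[3L] - table$K))
}

#' TC sagittal intersection from the inter-malleolar ratio
#'
#' The TC axis pierces the segment M1--M2 so that |M2-M1| / |M2-r1| equals the
#' anthropometric ratio `Rratio = W/w`; solving gives
#' `r1 = M2 - (M2 - M1) / Rratio`.
#'
#' @param M1,M2 3-vectors in cm.
#' @param Rratio Positive ratio.
#' @return 3-vector `r1`, collinear with M1--M2.
#' @export
r1_from_ratio <- function(M1, M2, Rratio) {
  M1 <- as_vec3(M1, "M1")
  M2 <- as_vec3(M2, "M2")
  if (!is.finite(Rratio) || Rratio == 0) {
    abort_ankle("`Rratio` must be non-zero", "degenerate_geometry")
  }
  if (norm3(M2 - M1) < 1e-12) {
    abort_ankle("M1 and M2 coincide: segment is degenerate",
                "degenerate_geometry")
  }
  M2 - (M2 - M1) / Rratio
}

#' ST sagittal intersection from the TC intersection
#'
#' Offsets `r1` by `Q` along an inclined in-sagittal-plane direction. The
#' default inclination is 41 degrees (the stated ST inclination); the
#' `"diagonal"` convention uses the 45-degree offset `(sqrt(2)/2) * (Q, 0, Q)`.
#'
#' @param r1 3-vector in cm.
#' @param Q Offset length in cm (non-negative).
#' @param inclination_deg Inclination angle in degrees (used by the
#'   `"inclined"` convention).
#' @param convention `"inclined"` (default, angle `inclination_deg`) or
#'   `"diagonal"` (45 degrees).
#' @return 3-vector `r2`.
#' @export
r2_from_r1 <- function(r1, Q, inclination_deg = 41,
                       convention = c("inclined", "diagonal")) {
  r1 <- as_vec3(r1, "r1")
  check_nonnegative(Q, "Q")
  convention <- match.arg(convention)
  theta <- deg2rad(if (convention == "diagonal") 45 else inclination_deg)
  r1 + Q * c(cos(theta), 0, sin(theta))
}

#' Platform vertices of the foot-attached equilateral triangle
#'
#' Places the three platform vertices on a circle of circumradius `rp` centred
#' at the platform centre `PM = (0, 0, -dm)`. The default angles (0, 120,
#' -120 degrees) give an equilateral triangle of edge `rp * sqrt(3)` whose
#' centroid is `PM`.
#'
#' @param rp Circumradius in cm (positive).
#' @param dm Distance from the base origin to the platform plane in cm
#'   (positive).
#' @param angles_deg Vertex angles in degrees (length 3).
#' @return A list of 3-vectors `A0`, `B0`, `C0`.
#' @export
platform_vertices <- function(rp, dm, angles_deg = c(0, 120, -120)) {
  check_positive(rp, "rp")
  check_positive(dm, "dm")
  if (length(angles_deg) != 3L) {
    abort_ankle("`angles_deg` must have length 3", "invalid_parameter")
  }
  th <- deg2rad(angles_deg)
  v <- lapply(th, function(a) c(rp * cos(a), rp * sin(a), -dm))
  names(v) <- c("A0", "B0", "C0")
  v
}

#' Rotate a coordinate seed axis by a sequence of elementary rotations
#'
#' Builds a joint-axis direction by applying successive active rotations about
#' coordinate axes to a seed coordinate axis, e.g. the TC direction is the z
#' axis rotated -80 degrees about x then -6 degrees about z; the ST direction
#' is the x axis rotated 41 degrees about y then 23 degrees about z.
#'
#' @param seed_axis `"x"`, `"y"` or `"z"`.
#' @param axes Character vector of rotation axes, applied in order.
#' @param angles_deg Numeric vector of rotation angles in degrees.
#' @return A unit 3-vector.
#' @examples
#' axis_direction_from_angles("z", c("x", "z"), c(-80, -6)) # TC default
#' axis_direction_from_angles("x", c("y", "z"), c(41, 23))  # ST default
#' @export
axis_direction_from_angles <- function(seed_axis, axes = character(),
                                       angles_deg = numeric()) {
  if (length(axes) != length(angles_deg)) {
    abort_ankle("`axes` and `angles_deg` must have the same length",
                "invalid_parameter")
  }
  v <- switch(seed_axis,
    x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
    abort_ankle("`seed_axis` must be 'x', 'y' or 'z'", "invalid_parameter")
  )
  for (i in seq_along(axes)) {
    v <- drop(rot_axis(axes[i], deg2rad(angles_deg[i])) %*% v)
  }
  v / norm3(v)
}

#' Marker-based TC axis reference
#'
#' Offsets the malleolar markers by the anthropometric means
#' (`M10 = MLP - (L, 0, K)`, `M20 = MMP - (-P, 0, O)`) and intersects the line
#' through them with the sagittal plane y = 0 to obtain the TC reference point
#' `r1`.
#'
#' @param MLP,MMP Marker 3-vectors in cm.
#' @param table An [anthro_table()].
#' @return A list with `M10`, `M20` and `r1` (with `r1[2] == 0`).
#' @export
tc_axis_reference <- function(MLP, MMP, table = anthro_table()) {
  MLP <- as_vec3(MLP, "MLP")
  MMP <- as_vec3(MMP, "MMP")
  M10 <- MLP - c(table$L, 0, table$K)
  M20 <- MMP - c(-table$P, 0, table$O)
  d <- M20 - M10
  if (norm3(d) < 1e-12) {
    abort_ankle("M10 and M20 coincide: no line to intersect",
                "degenerate_geometry")
  }
  if (abs(d[2L]) < 1e-12) {
    abort_ankle("segment M10-M20 is parallel to the sagittal plane",
                "no_intersection")
  }
  t_ <- -M10[2L] / d[2L]
  r1 <- M10 + t_ * d
  r1[2L] <- 0
  list(M10 = M10, M20 = M20, r1 = r1)
}

#' Build the full ankle reference geometry from body height
#'
#' Combines the anthropometric table, body-model proportions and the default
#' axis orientations into the set of reference points used by the kinematic
#' model and the device: the sagittal intersections `r1` (TC) and `r2` (ST),
#' the unit axis directions, the platform vertices `A0`, `B0`, `C0` and the
#' platform centre `PM`. Default malleolus markers are anatomically plausible
#' positions scaled with height (see the package vignette).
#'
#' @param H Body height in cm.
#' @param table An [anthro_table()].
#' @param rp Platform circumradius in cm; defaults to two thirds of the foot
#'   length, `(2/3) * foot_length_frac * H`.
#' @param MMP,MLP Optional malleolus marker overrides (3-vectors, cm).
#' @param tc_angles,st_angles Axis-orientation angle pairs in degrees.
#' @param r2_convention Passed to [r2_from_r1()].
#' @param knee_foot_frac,ankle_foot_frac,foot_width_frac,foot_length_frac
#'   Body-model proportions (fractions of H, each in (0, 1)).
#' @return An object of class `ankle_reference`.
#' @examples
#' ref <- ankle_reference(H = 175)
#' ref$r1
#' @export
ankle_reference <- function(H = 175, table = anthro_table(), rp = NULL,
                            MMP = NULL, MLP = NULL,
                            tc_angles = c(-80, -6), st_angles = c(41, 23),
                            r2_convention = "inclined",
                            knee_foot_frac = 0.285, ankle_foot_frac = 0.039,
                            foot_width_frac = 0.055, foot_length_frac = 0.152) {
  check_positive(H, "H")
  for (nm in c("knee_foot_frac", "ankle_foot_frac", "foot_width_frac",
               "foot_length_frac")) {
    f <- get(nm)
    if (!is.finite(f) || f <= 0 || f >= 1) {
      abort_ankle(sprintf("`%s` must lie in (0, 1)", nm), "invalid_parameter")
    }
  }
  dm <- knee_ankle_distance(H, knee_foot_frac, ankle_foot_frac)
  if (is.null(rp)) rp <- (2 / 3) * foot_length_frac * H
  check_positive(rp, "rp")
  sc <- H / 175
  if (is.null(MMP)) MMP <- c(0.2, 3.4, -19.8) * sc
  if (is.null(MLP)) MLP <- c(-0.8, -3.6, -20.5) * sc
  MMP <- as_vec3(MMP, "MMP")
  MLP <- as_vec3(MLP, "MLP")

  marker <- tc_axis_reference(MLP, MMP, table)
  r1 <- marker$r1
  r2 <- r2_from_r1(r1, table$Q, convention = r2_convention)
  omega_tc <- axis_direction_from_angles("z", c("x", "z"), tc_angles)
  omega_st <- axis_direction_from_angles("x", c("y", "z"), st_angles)
  verts <- platform_vertices(rp, dm)

  structure(list(
    H = H, table = table, dm = dm, rp = rp,
    MMP = MMP, MLP = MLP, M10 = marker$M10, M20 = marker$M20,
    r1 = r1, r2 = r2, omega_tc = omega_tc, omega_st = omega_st,
    A0 = verts$A0, B0 = verts$B0, C0 = verts$C0, PM = c(0, 0, -dm),
    P0 = c(0, 0, 0),
    fractions = c(knee_foot = knee_foot_frac, ankle_foot = ankle_foot_frac,
                  foot_width = foot_width_frac, foot_length = foot_length_frac)
  ), class = "ankle_reference")
}

#' @export
print.ankle_reference <- function(x, ...) {
  cat(sprintf("Ankle reference geometry (H = %.1f cm)\n", x$H))
  cat(sprintf("  dm = %.3f cm, rp = %.3f cm\n", x$dm, x$rp))
  cat(sprintf("  r1 (TC @ sagittal) = (%.3f, %.3f, %.3f) cm\n",
              x$r1[1], x$r1[2], x$r1[3]))
  cat(sprintf("  r2 (ST @ sagittal) = (%.3f, %.3f, %.3f) cm\n",
              x$r2[1], x$r2[2], x$r2[3]))
  cat(sprintf("  omega_tc = (%.4f, %.4f, %.4f)\n",
              x$omega_tc[1], x$omega_tc[2], x$omega_tc[3]))
  cat(sprintf("  omega_st = (%.4f, %.4f, %.4f)\n",
              x$omega_st[1], x$omega_st[2], x$omega_st[3]))
  invisible(x)
}
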