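# Synthetic capture generation: the forward chain POE -> wire lengths ->
# additive Gaussian length noise -> optional ADC round trip, standing in for
# the measurement hardware. Ground truth is kept alongside for testing.

#' Single-movement joint-angle path
#'
#' A smooth sweep of one joint from one range end to the other (half-cosine
#' time profile, continuous velocity) with the other joint held at zero:
#' pure plantar/dorsiflexion sweeps theta1 (TC), pure inversion/eversion
#' sweeps theta2 (ST).
#'
#' @param model An [ankle_model()].
#' @param movement `"plantar_dorsiflexion"` or `"inversion_eversion"`.
#' @param n_frames Number of samples (>= 2).
#' @return n x 2 matrix of (theta1, theta2) in radians.
#' @export
movement_path <- function(model, movement = c("plantar_dorsiflexion",
                                              "inversion_eversion"),
                          n_frames = 25L) {
  movement <- match.arg(movement)
  if (n_frames < 2L) abort_ankle("`n_frames` must be >= 2", "invalid_parameter")
  rng <- deg2rad(if (movement == "plantar_dorsiflexion") {
    model$theta1_range
  } else {
    model$theta2_range
  })
  u <- (1 - cos(seq(0, pi, length.out = n_frames))) / 2
  sweep_ <- rng[1L] + u * diff(rng)
  if (movement == "plantar_dorsiflexion") {
    cbind(theta1 = sweep_, theta2 = 0)
  } else {
    cbind(theta1 = 0, theta2 = sweep_)
  }
}

#' Simulate a draw-wire capture log
#'
#' For each sample of the joint-angle path: platform vertices by the product
#' of exponentials, exact wire lengths to the seven anchors, optional i.i.d.
#' Gaussian length noise, and an optional ADC round trip (inverse
#' calibration to counts, quantization, calibration back to cm). Relative
#' IMU channels are emulated from the platform-centre acceleration so the
#' jerk-based segmentation has a signal to work on. The generating angles
#' and exact vertices are retained in the `truth` attribute.
#'
#' @param model An [ankle_model()].
#' @param geom An `ankle_geometry`.
#' @param path n x 2 matrix of joint angles in radians (e.g.
#'   [movement_path()]).
#' @param noise_sigma Gaussian length-noise s.d. in cm (0 disables noise).
#' @param adc Optional [adc_spec()] for the quantization round trip.
#' @param calib Optional [calibration_params()] (required with `adc`).
#' @param seed Optional integer seed; with a fixed seed the log is
#'   reproducible bit for bit.
#' @param dt Sampling interval in s.
#' @return An `ankle_capture`: a data.frame with columns `t`,
#'   `lA1 ... lC3` (cm), `imu1`, `imu2`, carrying attributes `truth`
#'   (list with `theta` and `vertices`), `seed`, `noise_sigma` and
#'   `geometry_tag`.
#' @export
simulate_capture <- function(model, geom, path, noise_sigma = 0,
                             adc = NULL, calib = NULL, seed = NULL,
                             dt = 0.01) {
  path <- rbind(path)
  if (ncol(path) != 2L) {
    abort_ankle("`path` must be an n x 2 matrix of joint angles (radians)",
                "invalid_parameter")
  }
  check_nonnegative(noise_sigma, "noise_sigma")
  if (!is.null(adc) && is.null(calib)) {
    abort_ankle("an ADC round trip requires calibration parameters",
                "invalid_parameter")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(path)
  r1 <- deg2rad(model$theta1_range); r2 <- deg2rad(model$theta2_range)
  out_of_range <- path[, 1L] < r1[1L] - 1e-9 | path[, 1L] > r1[2L] + 1e-9 |
    path[, 2L] < r2[1L] - 1e-9 | path[, 2L] > r2[2L] + 1e-9

  sensors <- c("lA1", "lA2", "lA3", "lB1", "lB3", "lC1", "lC3")
  lengths <- matrix(NA_real_, n, 7L, dimnames = list(NULL, sensors))
  vertices <- array(NA_real_, c(n, 3L, 3L),
                    dimnames = list(NULL, c("A", "B", "C"), c("x", "y", "z")))
  pm <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    v <- fk_vertices(model, path[i, 1L], path[i, 2L])
    vertices[i, , ] <- v
    pm[i, ] <- colMeans(v)
    lengths[i, ] <- wire_lengths(geom, v)
  }
  if (noise_sigma > 0) {
    lengths <- lengths + matrix(stats::rnorm(n * 7L, sd = noise_sigma), n, 7L)
  }
  if (!is.null(adc)) {
    v_per_count <- 1 # counts are driven directly through the calibration line
    for (k in seq_len(7L)) {
      counts <- quantize_adc(invert_calibration(lengths[, k], calib) *
                               v_per_count / (2^adc$bits - 1) * adc$v_ref, adc)
      lengths[, k] <- apply_calibration(as.numeric(counts), calib)
    }
  }
  acc <- rbind(0, diff(rbind(0, diff(pm))) / dt^2)
  imu2 <- sqrt(rowSums(acc^2))
  df <- data.frame(t = (seq_len(n) - 1L) * dt, lengths,
                   imu1 = rep(0, n), imu2 = imu2)
  structure(df,
            class = c("ankle_capture", "data.frame"),
            truth = list(theta = path, vertices = vertices,
                         out_of_range = out_of_range),
            seed = seed, noise_sigma = noise_sigma,
            geometry_tag = geometry_tag(geom))
}

geometry_tag <- function(geom) {
  vals <- c(unlist(geom$anchors), unlist(geom$platform), geom$rm)
  sprintf("g%08x", sum(as.integer(abs(vals) * 1e4) %% 2147483L) %% .Machine$integer.max)
}

#' Solve every frame of a capture
#'
#' Runs [solve_platform()] on each row of a capture log and returns the
#' solved vertex positions in long format, with the platform centre `PM`
#' appended as the centroid of the solved triangle.
#'
#' @param geom An `ankle_geometry`.
#' @param capture An `ankle_capture` (or data.frame with the seven length
#'   columns).
#' @param movement Movement label attached to the output.
#' @param drop_inconsistent Drop (with a summary warning) frames whose
#'   platform-edge cross-check fails, instead of aborting; frames with
#'   geometrically impossible lengths still abort.
#' @param ... Passed to [solve_platform()].
#' @return A data.frame with columns `label`, `movement`, `t`, `x`, `y`, `z`.
#' @export
solve_capture <- function(geom, capture,
                          movement = c("plantar_dorsiflexion",
                                       "inversion_eversion"),
                          drop_inconsistent = TRUE, ...) {
  movement <- match.arg(movement)
  sensors <- c("lA1", "lA2", "lA3", "lB1", "lB3", "lC1", "lC3")
  if (!all(sensors %in% names(capture))) {
    abort_ankle("capture must contain the seven length columns", "schema")
  }
  tvec <- if ("t" %in% names(capture)) capture$t else seq_len(nrow(capture))
  dropped <- 0L
  rows <- lapply(seq_len(nrow(capture)), function(i) {
    sol <- if (drop_inconsistent) {
      tryCatch(solve_platform(geom, unlist(capture[i, sensors]), ...),
               anklekin_ambiguous_apex = function(e) NULL)
    } else {
      solve_platform(geom, unlist(capture[i, sensors]), ...)
    }
    if (is.null(sol)) {
      dropped <<- dropped + 1L
      return(NULL)
    }
    v <- rbind(sol$vertices, PM = colMeans(sol$vertices))
    data.frame(label = c("A", "B", "C", "PM"), movement = movement,
               t = tvec[i], x = v[, 1L], y = v[, 2L], z = v[, 3L],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  if (dropped > 0L) {
    warning(sprintf("dropped %d of %d frames failing the platform-edge cross-check",
                    dropped, nrow(capture)), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    abort_ankle("no frame of the capture could be solved consistently", "data")
  }
  out
}

#' End-to-end synthetic axis-estimation experiment
#'
#' Simulates one pure plantar/dorsiflexion and one pure inversion/eversion
#' capture, solves every frame by trilateration, and estimates both axes
#' from the solved vertex trajectories (A, B, C and the platform centre).
#'
#' @param model An [ankle_model()].
#' @param geom An `ankle_geometry`.
#' @param n_frames Samples per movement.
#' @param noise_sigma Length-noise s.d. in cm.
#' @param seed Optional integer seed.
#' @param ewma_alpha EWMA weight applied per length channel before solving,
#'   mirroring the acquisition firmware's filter; `NULL` disables it. On a
#'   slow continuous sweep the filter lag displaces samples along the
#'   trajectory arc, not off its plane, so it suppresses noise without
#'   biasing the axis fit.
#' @return A list with `axes` (from [estimate_axes()]), `solved` (the long
#'   data.frame of solved positions) and `captures`.
#' @export
run_axis_experiment <- function(model, geom, n_frames = 25L, noise_sigma = 0,
                                seed = NULL, ewma_alpha = 0.2) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  caps <- list()
  solved <- list()
  for (mv in c("plantar_dorsiflexion", "inversion_eversion")) {
    cap <- simulate_capture(model, geom, movement_path(model, mv, n_frames),
                            noise_sigma = noise_sigma)
    caps[[mv]] <- cap
    if (!is.null(ewma_alpha) && noise_sigma > 0) {
      for (ch in c("lA1", "lA2", "lA3", "lB1", "lB3", "lC1", "lC3")) {
        cap[[ch]] <- ewma(cap[[ch]], ewma_alpha)
      }
    }
    solved[[mv]] <- solve_capture(geom, cap, movement = mv)
  }
  solved_df <- do.call(rbind, unname(solved))
  list(axes = estimate_axes(solved_df), solved = solved_df, captures = caps)
}

#' Angular separation between two axis directions
#'
#' Sign-insensitive angle (radians) between two direction vectors; axis
#' directions recovered from circle normals are defined only up to sign.
#'
#' @param a,b Direction 3-vectors.
#' @return Angle in radians in `[0, pi/2]`.
#' @export
axis_angle_error <- function(a, b) {
  a <- unit3(as_vec3(a, "a")); b <- unit3(as_vec3(b, "b"))
  acos(clamp(abs(sum(a * b)), 0, 1))
}
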