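# Configuration and capture-file I/O. Units at file boundaries: cm and
# degrees; CSV dialect: comma-separated, '.' decimal, UTF-8, header required.

default_run_config <- function() {
  list(
    anthropometry = list(
      H = 175, K = 1.2, L = 1.1, O = 1.6, P = 1.0, Q = 0.5, Rratio = 0.54,
      rp = NULL, tc_angles = c(-80, -6), st_angles = c(41, 23),
      r2_convention = "inclined"
    ),
    geometry = list(rm = 2, anchor_radius = NULL, apex_side = "below",
                    edge_tol = 0.5),
    simulation = list(theta1_range = c(-15, 15), theta2_range = c(-15, 15),
                      n_frames = 25, noise_sigma = 0.05, seed = 1, dt = 0.01,
                      movement = "plantar_dorsiflexion"),
    fitting = list(min_arc_deg = 5)
  )
}

validate_config <- function(cfg) {
  defaults <- default_run_config()
  bad_block <- setdiff(names(cfg), names(defaults))
  if (length(bad_block)) {
    abort_ankle(sprintf("unknown config block(s): %s",
                        paste(bad_block, collapse = ", ")), "schema")
  }
  merged <- defaults
  for (blk in names(cfg)) {
    unknown <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
    if (length(unknown)) {
      abort_ankle(sprintf("unknown key(s) in `%s`: %s", blk,
                          paste(unknown, collapse = ", ")), "schema")
    }
    for (key in names(cfg[[blk]])) {
      merged[[blk]][[key]] <- cfg[[blk]][[key]]
    }
  }
  a <- merged$anthropometry
  chk <- function(ok, key, what) {
    if (!ok) abort_ankle(sprintf("config key `%s` %s", key, what), "schema")
  }
  chk(is.numeric(a$H) && a$H > 0, "anthropometry.H", "must be positive")
  for (key in c("K", "L", "O", "P", "Q")) {
    chk(is.numeric(a[[key]]) && a[[key]] >= 0,
        paste0("anthropometry.", key), "must be non-negative")
  }
  chk(is.numeric(a$Rratio) && a$Rratio > 0, "anthropometry.Rratio",
      "must be positive")
  if (!is.null(a$rp)) chk(is.numeric(a$rp) && a$rp > 0, "anthropometry.rp",
                          "must be positive")
  for (key in c("tc_angles", "st_angles")) {
    chk(is.numeric(a[[key]]) && length(a[[key]]) == 2L,
        paste0("anthropometry.", key), "must be two angles (deg)")
  }
  chk(a$r2_convention %in% c("inclined", "diagonal"),
      "anthropometry.r2_convention", "must be 'inclined' or 'diagonal'")
  g <- merged$geometry
  chk(is.numeric(g$rm) && g$rm > 0, "geometry.rm", "must be positive")
  if (!is.null(g$anchor_radius)) {
    chk(is.numeric(g$anchor_radius) && g$anchor_radius > 0,
        "geometry.anchor_radius", "must be positive")
  }
  chk(g$apex_side %in% c("below", "above"), "geometry.apex_side",
      "must be 'below' or 'above'")
  chk(is.numeric(g$edge_tol) && g$edge_tol > 0, "geometry.edge_tol",
      "must be positive")
  s <- merged$simulation
  for (key in c("theta1_range", "theta2_range")) {
    chk(is.numeric(s[[key]]) && length(s[[key]]) == 2L &&
          s[[key]][1L] < s[[key]][2L],
        paste0("simulation.", key), "must be an increasing interval (deg)")
  }
  chk(is.numeric(s$n_frames) && s$n_frames >= 2, "simulation.n_frames",
      "must be >= 2")
  chk(is.numeric(s$noise_sigma) && s$noise_sigma >= 0,
      "simulation.noise_sigma", "must be non-negative")
  chk(is.numeric(s$dt) && s$dt > 0, "simulation.dt", "must be positive")
  chk(s$movement %in% c("plantar_dorsiflexion", "inversion_eversion", "both"),
      "simulation.movement",
      "must be 'plantar_dorsiflexion', 'inversion_eversion' or 'both'")
  chk(is.numeric(merged$fitting$min_arc_deg) && merged$fitting$min_arc_deg >= 0,
      "fitting.min_arc_deg", "must be non-negative")
  structure(merged, class = "ankle_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON configuration, fills every missing
#' key with its documented default and validates the result; unknown keys
#' are rejected and validation errors name the offending key.
#'
#' @param path Path to the config file.
#' @return An object of class `ankle_config` (a fully defaulted nested
#'   list with blocks `anthropometry`, `geometry`, `simulation`, `fitting`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort_ankle(sprintf("config file not found: %s", path), "missing_file")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  validate_config(cfg)
}

#' Save a run configuration
#'
#' @param config An `ankle_config` (or compatible nested list).
#' @param path Output path; format chosen by extension (`.json` else YAML).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  config <- unclass(validate_config(unclass(config)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}

#' Build model and device geometry from a configuration
#'
#' @param config An `ankle_config`.
#' @return A list with `reference`, `model` and `geometry`.
#' @export
config_to_model <- function(config) {
  a <- config$anthropometry
  ref <- ankle_reference(H = a$H,
                         table = anthro_table(a$K, a$L, a$O, a$P, a$Q, a$Rratio),
                         rp = a$rp, tc_angles = a$tc_angles,
                         st_angles = a$st_angles,
                         r2_convention = a$r2_convention)
  model <- ankle_model(ref, theta1_range = config$simulation$theta1_range,
                       theta2_range = config$simulation$theta2_range)
  geom <- default_device_geometry(ref, rm = config$geometry$rm,
                                  anchor_radius = config$geometry$anchor_radius)
  list(reference = ref, model = model, geometry = geom)
}

capture_columns <- c("t", "lA1", "lA2", "lA3", "lB1", "lB3", "lC1", "lC3")

#' Write a capture log as CSV
#'
#' Numeric fields are written with 17 significant digits so a write/read
#' round trip is lossless.
#'
#' @param log Capture data.frame (columns `t`, `lA1 ... lC3`, optionally
#'   `imu1`, `imu2`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_capture_csv <- function(log, path) {
  if (!all(capture_columns %in% names(log))) {
    abort_ankle(sprintf("capture must contain columns %s",
                        paste(capture_columns, collapse = ", ")), "schema")
  }
  keep <- c(capture_columns,
            intersect(c("imu1", "imu2", "movement"), names(log)))
  chr <- vapply(log[keep], function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(log)))
  chr <- rbind(chr)
  utils::write.table(chr, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = keep)
  invisible(path)
}

#' Read a capture log from CSV
#'
#' Validates the header, numeric parsing (malformed rows are reported with
#' their line numbers) and strictly increasing timestamps.
#'
#' @param path CSV path.
#' @return A data.frame of class `ankle_capture`.
#' @export
read_capture_csv <- function(path) {
  if (!file.exists(path)) {
    abort_ankle(sprintf("capture file not found: %s", path), "missing_file")
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) abort_ankle(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e)), "data")
  )
  if (nrow(df) == 0L) abort_ankle("capture file is empty", "empty_log")
  missing <- setdiff(capture_columns, names(df))
  if (length(missing)) {
    abort_ankle(sprintf("capture is missing column(s): %s",
                        paste(missing, collapse = ", ")), "schema")
  }
  for (col in intersect(c(capture_columns, "imu1", "imu2"), names(df))) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad)) {
      abort_ankle(sprintf("malformed numeric value(s) in column `%s`, line(s) %s",
                          col, paste(bad + 1L, collapse = ", ")), "data")
    }
    df[[col]] <- vals
  }
  if (any(diff(df$t) <= 0)) {
    abort_ankle("timestamps must be strictly increasing", "data")
  }
  class(df) <- c("ankle_capture", "data.frame")
  df
}

#' Write an axis report as JSON
#'
#' @param axes Result of [estimate_axes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_axis_report <- function(axes, path) {
  pack <- function(ax) {
    if (is.null(ax)) return(NULL)
    list(r = ax$point_r, omega = ax$direction,
         plucker = unname(ax$plucker),
         median_center = ax$median_center,
         per_trajectory = lapply(ax$circles, function(cf) {
           list(label = cf$label, movement = cf$movement, center = cf$center,
                normal = cf$normal, radius = cf$radius,
                rms_residual = cf$rms_residual)
         }))
  }
  jsonlite::write_json(list(tc = pack(axes$tc), st = pack(axes$st),
                            partial = isTRUE(axes$partial)),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Format an axis as a flat Pluecker line string
#'
#' @param plucker Named or plain 6-vector `[wx wy wz mx my mz]`.
#' @param digits Significant digits.
#' @return A string `"[wx: wy: wz: mx: my: mz]"`.
#' @export
format_plucker <- function(plucker, digits = 3L) {
  sprintf("[%s]", paste(signif(as.numeric(plucker), digits), collapse = ": "))
}
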