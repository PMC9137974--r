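# Draw-wire sensor chain: drum geometry -> resistance -> amplified voltage ->
# ADC counts -> calibration back to cm, plus EWMA filtering and capture
# segmentation.

#' Maximal wire extension of a draw-wire drum
#'
#' @param drum_diameter Drum diameter in cm (positive).
#' @param usable_turns Number of usable spring turns (positive).
#' @return Length in cm, `usable_turns * drum_diameter * pi`.
#' @examples
#' max_extension(3.8, 4) # ~47.75
#' @export
max_extension <- function(drum_diameter, usable_turns) {
  check_positive(drum_diameter, "drum_diameter")
  check_positive(usable_turns, "usable_turns")
  usable_turns * drum_diameter * pi
}

#' Potentiometer resistance per turn
#'
#' @param Rn Nominal resistance in Ohm (non-negative).
#' @param n_turns Number of potentiometer turns (>= 1).
#' @return Ohm per turn.
#' @examples
#' resistance_per_turn(2200, 10) # 220
#' @export
resistance_per_turn <- function(Rn, n_turns) {
  check_nonnegative(Rn, "Rn")
  if (!is.finite(n_turns) || n_turns < 1) {
    abort_ankle("`n_turns` must be >= 1", "division_by_zero")
  }
  Rn / n_turns
}

#' Two-op-amp instrumentation amplifier gain
#'
#' Standard two-amplifier instrumentation topology:
#' `Av = 1 + R2/R1 + 2 R2/RG`.
#'
#' @param R1,R2,RG Resistances in Ohm (`R1`, `RG` positive, `R2`
#'   non-negative).
#' @return Dimensionless voltage gain.
#' @examples
#' instrumentation_gain(1e3, 1e5, 5e3) # 141
#' @export
instrumentation_gain <- function(R1, R2, RG) {
  check_positive(R1, "R1")
  check_nonnegative(R2, "R2")
  check_positive(RG, "RG")
  1 + R2 / R1 + 2 * R2 / RG
}

#' Amplifier output voltage
#'
#' @param gain Voltage gain.
#' @param vi Input voltage in V.
#' @return `gain * vi` in V.
#' @export
output_voltage <- function(gain, vi) gain * vi

#' ADC specification
#'
#' @param bits Resolution in bits (>= 1).
#' @param v_ref Reference (full-scale) voltage in V (positive).
#' @return An object of class `adc_spec`.
#' @export
adc_spec <- function(bits = 10L, v_ref = 5) {
  if (!is.finite(bits) || bits < 1) {
    abort_ankle("`bits` must be >= 1", "invalid_parameter")
  }
  check_positive(v_ref, "v_ref")
  structure(list(bits = as.integer(bits), v_ref = v_ref), class = "adc_spec")
}

#' Quantize a voltage to ADC counts
#'
#' Clamps to `[0, v_ref]` and rounds to the nearest of `2^bits` levels;
#' saturated samples are flagged in the `"saturated"` attribute.
#'
#' @param v Voltage(s) in V.
#' @param spec An [adc_spec()].
#' @return Integer counts in `[0, 2^bits - 1]` with attribute `saturated`.
#' @export
quantize_adc <- function(v, spec = adc_spec()) {
  saturated <- v < 0 | v > spec$v_ref
  counts <- as.integer(round(clamp(v, 0, spec$v_ref) / spec$v_ref *
                               (2^spec$bits - 1)))
  attr(counts, "saturated") <- saturated
  counts
}

#' Voltage corresponding to ADC counts
#'
#' @param counts Integer counts.
#' @param spec An [adc_spec()].
#' @return Voltage(s) in V.
#' @export
dequantize_adc <- function(counts, spec = adc_spec()) {
  as.numeric(counts) / (2^spec$bits - 1) * spec$v_ref
}

#' Per-sensor linear calibration
#'
#' Length in cm from a digital reading: `l = d + m * s` with offset `d` (cm)
#' and scale `s` (cm per count).
#'
#' @param d Offset in cm.
#' @param s Scale in cm per digital count (non-zero).
#' @return An object of class `calibration_params`.
#' @export
calibration_params <- function(d = 0, s = 1) {
  if (!is.finite(s) || s == 0) {
    abort_ankle("calibration scale `s` must be non-zero", "invalid_parameter")
  }
  structure(list(d = d, s = s), class = "calibration_params")
}

#' Apply a linear calibration to digital counts
#'
#' @param counts Numeric digital readings.
#' @param params A [calibration_params()].
#' @return Lengths in cm.
#' @export
apply_calibration <- function(counts, params) {
  params$d + as.numeric(counts) * params$s
}

#' Invert a linear calibration (length to counts, unrounded)
#'
#' @param lengths Lengths in cm.
#' @param params A [calibration_params()].
#' @return Unrounded digital values.
#' @export
invert_calibration <- function(lengths, params) {
  (as.numeric(lengths) - params$d) / params$s
}

#' Fit a linear calibration from (counts, length) pairs
#'
#' Ordinary least squares line per sensor; needs at least two distinct count
#' values.
#'
#' @param counts Digital readings.
#' @param lengths Reference lengths in cm (e.g. caliper measurements).
#' @return A [calibration_params()] with an added `residuals` field (cm).
#' @export
fit_calibration <- function(counts, lengths) {
  counts <- as.numeric(counts)
  lengths <- as.numeric(lengths)
  if (length(counts) != length(lengths) || length(counts) < 2L ||
      length(unique(counts)) < 2L) {
    abort_ankle("calibration needs >= 2 pairs with distinct count values",
                "insufficient_data")
  }
  fit <- stats::lm.fit(cbind(1, counts), lengths)
  out <- calibration_params(d = unname(fit$coefficients[1L]),
                            s = unname(fit$coefficients[2L]))
  out$residuals <- unname(fit$residuals)
  out
}

#' Exponentially weighted moving average
#'
#' First-order recursive low-pass: `y[1] = x[1]`,
#' `y[t] = alpha x[t] + (1 - alpha) y[t-1]`.
#'
#' @param x Numeric series.
#' @param alpha Smoothing weight in (0, 1].
#' @return Filtered series, same length as `x`.
#' @export
ewma <- function(x, alpha = 0.2) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    abort_ankle("`alpha` must lie in (0, 1]", "invalid_parameter")
  }
  x <- as.numeric(x)
  if (length(x) <= 1L || alpha == 1) return(x)
  y <- stats::filter(alpha * x[-1L], 1 - alpha, method = "recursive",
                     init = x[1L])
  c(x[1L], as.numeric(y))
}

#' Segment a capture by jerk of the relative IMU signal
#'
#' Computes the relative reading `dr = imu2 - imu1` per sample and the jerk
#' `|dr[i] - dr[i-1]|`; a movement segment opens when the jerk rises above
#' `epsilon` and closes at the next return to `<= epsilon` (the
#' zero-crossing rule with a numeric tolerance).
#'
#' @param imu1,imu2 Numeric acceleration series of equal length (>= 3).
#' @param epsilon Jerk threshold (normalized acceleration units).
#' @return A data.frame with columns `start` and `end` (sample indices into
#'   the original series), one row per detected segment.
#' @export
segment_capture <- function(imu1, imu2, epsilon = 1e-3) {
  if (length(imu1) != length(imu2) || length(imu1) < 3L) {
    abort_ankle("need >= 3 paired IMU samples", "invalid_parameter")
  }
  dr <- imu2 - imu1
  jerk <- abs(diff(dr)) # jerk[i] pairs with sample i + 1
  active <- jerk > epsilon
  starts <- integer(0L)
  ends <- integer(0L)
  open_at <- NA_integer_
  for (i in seq_along(active)) {
    if (active[i] && is.na(open_at)) {
      open_at <- i + 1L
    } else if (!active[i] && !is.na(open_at)) {
      starts <- c(starts, open_at)
      ends <- c(ends, i + 1L)
      open_at <- NA_integer_
    }
  }
  if (!is.na(open_at)) { # still moving at the end of the record
    starts <- c(starts, open_at)
    ends <- c(ends, length(imu1))
  }
  data.frame(start = starts, end = ends)
}
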