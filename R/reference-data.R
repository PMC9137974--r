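#' Bundled example circle-fit summaries
#'
#' Circle-fit results (centre, plane normal, radius per tracked point A, B,
#' C and platform centre PM) recorded from a prototype capture session with
#' a healthy adult, one set per movement group. They exercise the axis
#' post-processing chain (median aggregation, sagittal intersection,
#' Pluecker packing) without needing the capture hardware.
#'
#' @return A named list of lists of `ankle_circle_fit` objects, keyed by
#'   movement group.
#' @examples
#' fits <- reference_circle_fits()
#' aggregate_axis(fits$inversion_eversion)
#' @export
reference_circle_fits <- function() {
  path <- system.file("extdata", "circle_fit_reference.csv",
                      package = "anklekin", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(center = c(df$cx[i], df$cy[i], df$cz[i]),
                   normal = unit3(c(df$nx[i], df$ny[i], df$nz[i])),
                   radius = df$radius_cm[i], rms_residual = NA_real_,
                   arc_deg = NA_real_, n_points = NA_integer_,
                   label = df$trajectory[i], movement = df$movement[i]),
              class = "ankle_circle_fit")
  })
  split(fits, df$movement)
}
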