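#' Acquisition calibration
#'
#' Bundles the acquisition constants needed to convert pixel/frame
#' measurements into physical units, plus the anatomical orientation of the
#' image. The defaults correspond to a stereomicroscope recording at 5
#' frames per second with 110.85 pixels per millimetre and the oviductal end
#' of the horn on the left edge of the frame.
#'
#' @param fps Frames per second of the recording. Must be positive.
#' @param px_per_mm Pixels per millimetre. Must be positive.
#' @param orientation Which image edge holds the oviductal end of the horn,
#'   `"left"` or `"right"`. All spatiotemporal maps are re-oriented so that
#'   the spatial axis runs oviduct to cervix; with `"left"` (the default)
#'   no flip is needed and a positive ridge slope means a wave travelling
#'   toward the cervix.
#'
#' @return A `calibration` object (a validated list).
#' @examples
#' cal <- calibration()
#' px_to_mm(110.85, cal)   # 1 mm
#' frames_to_s(1500, cal)  # 300 s
#' @export
calibration <- function(fps = 5, px_per_mm = 110.85, orientation = c("left", "right")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0) {
    abort("`fps` must be a single positive number.", class = "myowave_validation_error")
  }
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1 || !is.finite(px_per_mm) || px_per_mm <= 0) {
    abort("`px_per_mm` must be a single positive number.", class = "myowave_validation_error")
  }
  structure(
    list(fps = as.numeric(fps), px_per_mm = as.numeric(px_per_mm), orientation = orientation),
    class = "myowave_calibration"
  )
}

#' @export
print.myowave_calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> %g fps, %g px/mm, oviduct on the %s\n",
    x$fps, x$px_per_mm, x$orientation
  ))
  invisible(x)
}

check_odd_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 || x %% 2 != 1) {
    abort(sprintf("`%s` must be a positive odd integer.", name),
          class = "myowave_validation_error")
  }
  as.integer(x)
}

#' Boundary-detection parameters
#'
#' Tuning parameters for organ boundary tracing: Gaussian pre-smoothing
#' sizes, the Sobel aperture and vertical-edge weight of the edge index,
#' the cumulative edge-index crossing threshold, and the spline knot
#' spacing used to regularise the traced boundaries.
#'
#' Kernel "size" means window length; the Gaussian sigma follows the usual
#' automatic rule `0.3 * ((size - 1) / 2 - 1) + 0.8` so that stating the
#' size alone fully determines the filter.
#'
#' @param t_kernel Temporal Gaussian window (frames, odd). Default 3.
#' @param s_kernel Spatial Gaussian window (pixels, odd, applied along rows
#'   and columns). Default 5.
#' @param sobel_size Sobel aperture (odd). Default 5.
#' @param vertical_weight Multiplier on the vertical Sobel response in the
#'   edge index `S_h + vertical_weight * S_v`. Default 2.
#' @param threshold Crossing value for the normalised cumulative edge index;
#'   the first (top-down) and last (bottom-up) crossings mark the upper and
#'   lower boundaries. Default 2.
#' @param knot_spacing Columns between cubic-spline knots when smoothing
#'   raw boundaries. Default 10.
#'
#' @return A `boundary_params` object.
#' @export
boundary_params <- function(t_kernel = 3, s_kernel = 5, sobel_size = 5,
                            vertical_weight = 2, threshold = 2, knot_spacing = 10) {
  t_kernel <- check_odd_positive(t_kernel, "t_kernel")
  s_kernel <- check_odd_positive(s_kernel, "s_kernel")
  sobel_size <- check_odd_positive(sobel_size, "sobel_size")
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("`threshold` must be positive.", class = "myowave_validation_error")
  }
  if (!is.numeric(knot_spacing) || knot_spacing < 2) {
    abort("`knot_spacing` must be >= 2.", class = "myowave_validation_error")
  }
  structure(
    list(
      t_kernel = t_kernel, s_kernel = s_kernel, sobel_size = sobel_size,
      vertical_weight = as.numeric(vertical_weight),
      threshold = as.numeric(threshold), knot_spacing = as.integer(knot_spacing)
    ),
    class = "myowave_boundary_params"
  )
}

#' Map-enhancement parameters
#'
#' Parameters of the change-detection pipeline applied to a raw
#' spatiotemporal map: Sobel aperture for gradient magnitude, the window of
#' the centred moving average subtracted along space (high-pass detrend),
#' and the window of the centred moving average applied along time
#' (low-pass denoise).
#'
#' @param change_kernel Sobel aperture on the space-by-time matrix (odd).
#'   Default 5.
#' @param spatial_detrend_window Columns in the spatial detrend window
#'   (odd). Default 51.
#' @param temporal_lowpass_window Frames in the temporal low-pass window
#'   (odd, smaller than the detrend window). Default 5.
#'
#' @return An `enhance_params` object.
#' @export
enhance_params <- function(change_kernel = 5, spatial_detrend_window = 51,
                           temporal_lowpass_window = 5) {
  change_kernel <- check_odd_positive(change_kernel, "change_kernel")
  spatial_detrend_window <- check_odd_positive(spatial_detrend_window, "spatial_detrend_window")
  temporal_lowpass_window <- check_odd_positive(temporal_lowpass_window, "temporal_lowpass_window")
  if (spatial_detrend_window <= temporal_lowpass_window) {
    abort("`spatial_detrend_window` must exceed `temporal_lowpass_window`.",
          class = "myowave_validation_error")
  }
  structure(
    list(
      change_kernel = change_kernel,
      spatial_detrend_window = spatial_detrend_window,
      temporal_lowpass_window = temporal_lowpass_window
    ),
    class = "myowave_enhance_params"
  )
}

#' ROUT outlier-removal parameters
#'
#' @param q Maximum desired false discovery rate, in (0, 0.5). Default 0.01
#'   (the conventional "Q = 1%").
#' @param max_iterations Maximum remove-and-refit passes. Default 10.
#'
#' @return A `rout_params` object.
#' @export
rout_params <- function(q = 0.01, max_iterations = 10) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 0.5) {
    abort("`q` must lie strictly between 0 and 0.5.", class = "myowave_validation_error")
  }
  if (!is.numeric(max_iterations) || max_iterations < 1) {
    abort("`max_iterations` must be >= 1.", class = "myowave_validation_error")
  }
  structure(list(q = as.numeric(q), max_iterations = as.integer(max_iterations)),
            class = "myowave_rout_params")
}

as_plain_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), as_plain_list) else x
}
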