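#' Unit conversions
#'
#' Pixel distances divide by the pixels-per-millimetre calibration; frame
#' counts divide by the frame rate.
#'
#' @param d Distance in pixels.
#' @param f Time in frames.
#' @param cal A [calibration()].
#'
#' @return Millimetres / seconds.
#' @examples
#' px_to_mm(110.85, calibration())  # 1
#' frames_to_s(1500, calibration()) # 300
#' @export
px_to_mm <- function(d, cal = calibration()) d / cal$px_per_mm

#' @rdname px_to_mm
#' @export
frames_to_s <- function(f, cal = calibration()) f / cal$fps

#' Waveform metrics from wave annotations
#'
#' Converts manually marked contraction waves on a spatiotemporal map into
#' physical waveform metrics. An annotation carries a ridge segment (two
#' `(column, frame)` endpoints traced along one wave crest), the spatial
#' extent of the wave band (`band_c0`, `band_c1`), and the frame at which
#' the next successive crest passes the ridge's starting column
#' (`next_ridge_t`, `NA` when the wave has no successor in the recording).
#'
#' Metrics:
#' \describe{
#'   \item{velocity_um_s}{absolute ridge slope, converted to um/s.}
#'   \item{direction}{sign of the slope on the oviduct-to-cervix axis:
#'     positive means toward the cervix, negative toward the oviduct;
#'     below `stationary_floor` um/s the wave is called stationary.}
#'   \item{amplitude_um}{spatial extent of the wave band along the horn,
#'     `|band_c1 - band_c0|` in um.}
#'   \item{period_s}{time between successive crests at the ridge's start
#'     column; `NA` without a successor.}
#'   \item{frequency_hz}{`1 / period_s`.}
#'   \item{wavelength_um}{`velocity_um_s / frequency_hz`.}
#' }
#'
#' @param annotations Tibble with columns `map_id`, `ridge_c0`, `ridge_t0`,
#'   `ridge_c1`, `ridge_t1`, `band_c0`, `band_c1`, `next_ridge_t`.
#' @param cal A [calibration()].
#' @param n_columns If given, a `segment` column (oviductal/middle/cervical
#'   third of the ridge midpoint) is added via [assign_segment()].
#' @param stationary_floor Velocity floor (um/s) below which a wave is
#'   labelled `stationary`. Default 0.1.
#'
#' @return A tibble of metrics, one row per annotation, in um, s, Hz and
#'   um/s.
#' @examples
#' ann <- tibble::tibble(
#'   map_id = "demo", ridge_c0 = 0, ridge_t0 = 0, ridge_c1 = 111,
#'   ridge_t1 = 50, band_c0 = 100, band_c1 = 121, next_ridge_t = 312.5
#' )
#' compute_metrics(ann, calibration())
#' @export
compute_metrics <- function(annotations, cal = calibration(), n_columns = NULL,
                            stationary_floor = 0.1) {
  check_columns(annotations, annotation_cols, "Annotation")
  if (nrow(annotations) == 0) {
    abort("Annotation table is empty.", class = "myowave_validation_error")
  }
  dt <- annotations$ridge_t1 - annotations$ridge_t0
  if (any(dt == 0)) {
    abort("Degenerate annotation: ridge endpoints share the same frame.",
          class = "myowave_validation_error")
  }
  bad_next <- !is.na(annotations$next_ridge_t) &
    annotations$next_ridge_t <= annotations$ridge_t0
  if (any(bad_next)) {
    abort("`next_ridge_t` must exceed the ridge's starting frame.",
          class = "myowave_validation_error")
  }
  um_per_px <- 1000 / cal$px_per_mm
  slope_px_frame <- (annotations$ridge_c1 - annotations$ridge_c0) / dt
  velocity <- abs(slope_px_frame) * cal$fps * um_per_px
  direction <- dplyr::case_when(
    velocity < stationary_floor ~ "stationary",
    slope_px_frame > 0 ~ "toward_cervix",
    TRUE ~ "toward_oviduct"
  )
  amplitude <- abs(annotations$band_c1 - annotations$band_c0) * um_per_px
  period <- (annotations$next_ridge_t - annotations$ridge_t0) / cal$fps
  frequency <- 1 / period
  wavelength <- velocity / frequency
  out <- tibble(
    map_id = annotations$map_id,
    amplitude_um = amplitude,
    period_s = period,
    frequency_hz = frequency,
    velocity_um_s = velocity,
    wavelength_um = wavelength,
    direction = direction
  )
  if (!is.null(n_columns)) {
    mid <- (annotations$ridge_c0 + annotations$ridge_c1) / 2
    out$segment <- assign_segment(mid, n_columns)
  }
  out
}

metric_names <- c("amplitude_um", "period_s", "frequency_hz",
                  "velocity_um_s", "wavelength_um")

#' Per-horn summary of waveform metrics
#'
#' Medians of each metric over the annotated waves of one horn, with the
#' number of waves contributing to each metric (waves without a successor
#' lack period-dependent metrics, so counts can differ per metric).
#'
#' @param metrics Metrics tibble from [compute_metrics()].
#'
#' @return A tibble with one row per metric: `metric`, `median`, `n`.
#' @export
summarize_metrics <- function(metrics) {
  if (nrow(metrics) == 0) {
    abort("Cannot summarise an empty metrics table.", class = "myowave_validation_error")
  }
  purrr::map_dfr(metric_names, function(m) {
    x <- metrics[[m]]
    tibble(metric = m, median = median(x, na.rm = TRUE), n = sum(!is.na(x)))
  })
}
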