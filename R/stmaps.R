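#' Spatiotemporal (Hovmoller) maps
#'
#' An `st_map` stores one per-column quantity of the organ — the pixel
#' distance between its boundaries ("area") or the mean fluorescence
#' intensity between them — as a space-by-time matrix: rows index position
#' along the horn (always oriented oviduct to cervix), columns index
#' frames. Travelling contraction waves appear as diagonal ridges whose
#' slope is the wave velocity. Masked (invalid) cells are `NA`.
#'
#' @param values Numeric matrix, space on rows and time on columns.
#' @param quantity One of `"area_px"`, `"mean_intensity"`,
#'   `"enhanced_area"`, `"enhanced_intensity"`.
#' @param calibration A [calibration()].
#'
#' @return An `st_map` object.
#' @export
st_map <- function(values, quantity, calibration = calibration()) {
  quantity <- match.arg(quantity,
                        c("area_px", "mean_intensity", "enhanced_area", "enhanced_intensity"))
  if (!is.matrix(values)) abort("`values` must be a matrix.", class = "myowave_validation_error")
  if (quantity == "area_px" && any(values < 0, na.rm = TRUE)) {
    abort("Area values must be non-negative.", class = "myowave_validation_error")
  }
  structure(
    list(values = values, quantity = quantity, calibration = calibration),
    class = "myowave_st_map"
  )
}

#' @export
print.myowave_st_map <- function(x, ...) {
  cat(sprintf(
    "<st_map> %s: %d positions x %d frames (%.2f mm x %.1f s), %d masked cells\n",
    x$quantity, nrow(x$values), ncol(x$values),
    nrow(x$values) / x$calibration$px_per_mm,
    ncol(x$values) / x$calibration$fps,
    sum(is.na(x$values))
  ))
  invisible(x)
}

#' @method tidy myowave_st_map
#' @export
tidy.myowave_st_map <- function(x, ...) {
  v <- x$values
  cal <- x$calibration
  tibble(
    column = rep(seq_len(nrow(v)) - 1L, times = ncol(v)),
    frame = rep(seq_len(ncol(v)) - 1L, each = nrow(v)),
    position_mm = rep((seq_len(nrow(v)) - 1L) / cal$px_per_mm, times = ncol(v)),
    time_s = rep((seq_len(ncol(v)) - 1L) / cal$fps, each = nrow(v)),
    value = as.vector(v),
    quantity = x$quantity
  )
}

#' @method glance myowave_st_map
#' @export
glance.myowave_st_map <- function(x, ...) {
  tibble(
    quantity = x$quantity,
    n_columns = nrow(x$values),
    n_frames = ncol(x$values),
    fps = x$calibration$fps,
    px_per_mm = x$calibration$px_per_mm,
    orientation = x$calibration$orientation,
    n_masked = sum(is.na(x$values)),
    value_median = median(x$values, na.rm = TRUE)
  )
}

#' @method autoplot myowave_st_map
#' @export
autoplot.myowave_st_map <- function(object, ...) {
  df <- tidy(object)
  lab <- c(
    area_px = "area (px)", mean_intensity = "mean intensity",
    enhanced_area = "enhanced area change", enhanced_intensity = "enhanced intensity change"
  )[[object$quantity]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_mm, y = .data$time_s,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "position along horn, oviduct → cervix (mm)",
                  y = "time (s)", fill = lab) +
    ggplot2::theme_minimal()
}

boundaries_to_grids <- function(boundaries) {
  nc <- max(boundaries$column) + 1L
  nt <- max(boundaries$frame) + 1L
  idx <- cbind(boundaries$column + 1L, boundaries$frame + 1L)
  up <- matrix(NA_real_, nc, nt); up[idx] <- boundaries$upper
  lo <- matrix(NA_real_, nc, nt); lo[idx] <- boundaries$lower
  valid <- matrix(FALSE, nc, nt); valid[idx] <- boundaries$valid
  list(upper = up, lower = lo, valid = valid, n_columns = nc, n_frames = nt)
}

orient_space <- function(m, cal) {
  if (cal$orientation == "right") m[rev(seq_len(nrow(m))), , drop = FALSE] else m
}

#' Area map from traced boundaries
#'
#' The "area" of a column is the pixel distance between the lower and
#' upper boundary — a unit-width proxy for the local cross-section of the
#' tube, so ridges in this map reflect circular-muscle (diameter-changing)
#' contractions. Invalid columns are masked.
#'
#' @param boundaries Boundary tibble from [trace_boundaries()].
#' @param cal A [calibration()]; with `orientation = "right"` the spatial
#'   axis is flipped so it always runs oviduct to cervix.
#'
#' @return An [st_map()] with quantity `"area_px"`.
#' @export
column_area <- function(boundaries, cal = calibration()) {
  g <- boundaries_to_grids(boundaries)
  v <- g$lower - g$upper
  v[!g$valid] <- NA_real_
  degenerate <- !is.na(v) & v <= 0
  v[degenerate] <- NA_real_
  st_map(orient_space(v, cal), "area_px", cal)
}

#' Mean-intensity map from the raw stack and traced boundaries
#'
#' For every column of every frame, averages the raw (never smoothed)
#' pixel intensities between the boundaries, over rows
#' `[ceiling(upper), floor(lower)]`. Local tissue compression concentrates
#' the fluorophore and raises this mean, so the map responds to both
#' circular and longitudinal contractions. Columns with no interior pixels
#' are masked.
#'
#' @param stack The raw [frame_stack()] the boundaries were traced on.
#' @param boundaries Boundary tibble from [trace_boundaries()].
#' @param cal A [calibration()].
#'
#' @return An [st_map()] with quantity `"mean_intensity"`.
#' @export
column_mean_intensity <- function(stack, boundaries, cal = calibration()) {
  stopifnot(inherits(stack, "myowave_frame_stack"))
  g <- boundaries_to_grids(boundaries)
  if (g$n_columns != stack_width(stack) || g$n_frames != n_frames(stack)) {
    abort("Boundaries and stack disagree on width or frame count.",
          class = "myowave_validation_error")
  }
  h <- stack_height(stack)
  v <- matrix(NA_real_, g$n_columns, g$n_frames)
  for (t in seq_len(g$n_frames)) {
    ok <- which(g$valid[, t])
    if (length(ok) == 0) next
    a <- ceiling(g$upper[ok, t]) + 1L          # 1-based first interior row
    b <- floor(g$lower[ok, t]) + 1L            # 1-based last interior row
    keep <- b >= a
    ok <- ok[keep]; a <- a[keep]; b <- b[keep]
    if (length(ok) == 0) next
    cs <- apply(stack$frames[, , t], 2, cumsum)
    tot <- cs[cbind(b, ok)] - ifelse(a > 1, cs[cbind(pmax(a - 1L, 1L), ok)], 0)
    v[ok, t] <- tot / (b - a + 1)
  }
  st_map(orient_space(v, cal), "mean_intensity", cal)
}

# constant-extrapolating linear fill along the space axis so the Sobel step
# has no NA holes; masked cells are restored afterwards
fill_space_na <- function(v) {
  apply(v, 2, function(col) {
    ok <- which(!is.na(col))
    if (length(ok) == 0) return(rep(0, length(col)))
    if (length(ok) == length(col)) return(col)
    stats::approx(ok, col[ok], xout = seq_along(col), rule = 2)$y
  })
}

#' Enhance a spatiotemporal map for wave marking
#'
#' Change-detection pipeline applied to a raw map: (1) subtraction of a
#' centred moving average along the spatial axis, removing the organ's
#' slowly varying baseline profile so it cannot leak into the gradients;
#' (2) Sobel gradient magnitude at the stated aperture on the space-by-time
#' matrix, which turns travelling waves into high-valued diagonal ridges
#' regardless of travel direction; (3) a centred moving average along time,
#' suppressing residual frame-to-frame noise. Masked cells are excluded
#' from the moving-average windows and stay masked in the output.
#'
#' @param map An [st_map()] with quantity `"area_px"` or `"mean_intensity"`.
#' @param params An [enhance_params()].
#'
#' @return An [st_map()] with quantity `"enhanced_area"` or
#'   `"enhanced_intensity"`.
#' @export
enhance_map <- function(map, params = enhance_params()) {
  stopifnot(inherits(map, "myowave_st_map"))
  v <- map$values
  if (any(dim(v) < params$change_kernel)) {
    abort(sprintf("Map (%d x %d) is smaller than the change kernel (%d).",
                  nrow(v), ncol(v), params$change_kernel),
          class = "myowave_size_error")
  }
  nas <- is.na(v)
  v <- v - moving_average_axis(v, params$spatial_detrend_window, axis = 1)
  filled <- fill_space_na(v)
  gx <- sobel_response(filled, params$change_kernel, axis = 1)
  gt <- sobel_response(filled, params$change_kernel, axis = 2)
  g <- sqrt(gx^2 + gt^2)
  g[nas] <- NA_real_
  g <- moving_average_axis(g, params$temporal_lowpass_window, axis = 2)
  quantity <- if (map$quantity %in% c("area_px", "enhanced_area")) {
    "enhanced_area"
  } else {
    "enhanced_intensity"
  }
  st_map(g, quantity, map$calibration)
}
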