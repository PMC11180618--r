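#' Smooth a frame stack for boundary detection
#'
#' Applies Gaussian smoothing along time (window `t_kernel`) and along both
#' spatial axes (window `s_kernel`) to suppress sensor noise before edge
#' detection. The smoothed stack is used only to locate the organ's
#' boundaries; intensity analyses always run on the raw stack, because
#' smoothing dilutes exactly the local intensity changes they measure.
#'
#' @param stack A [frame_stack()].
#' @param params A [boundary_params()].
#'
#' @return A smoothed [frame_stack()].
#' @export
smooth_stack <- function(stack, params = boundary_params()) {
  stopifnot(inherits(stack, "myowave_frame_stack"))
  if (n_frames(stack) < params$t_kernel) {
    abort(sprintf("Stack has %d frames but the temporal kernel needs %d.",
                  n_frames(stack), params$t_kernel),
          class = "myowave_insufficient_frames_error")
  }
  f <- stack$frames
  f <- convolve_axis(f, gaussian_kernel(params$t_kernel), 3)
  f <- convolve_axis(f, gaussian_kernel(params$s_kernel), 1)
  f <- convolve_axis(f, gaussian_kernel(params$s_kernel), 2)
  frame_stack(pmin(pmax(f, 0), 255), frame_interval = stack$frame_interval)
}

#' Weighted Sobel edge index of a frame
#'
#' Computes `S_h + vertical_weight * S_v`, where `S_h` is the Sobel
#' response to horizontal edges (intensity changing down the rows) and
#' `S_v` the response to vertical edges (intensity changing across the
#' columns), both at the aperture in `params`. Weighting the vertical
#' response combines the two into the single edge-index image that drives
#' boundary detection.
#'
#' @param frame A numeric matrix (one grayscale frame), at least
#'   `sobel_size` pixels in each dimension.
#' @param params A [boundary_params()].
#'
#' @return A numeric matrix of the same shape.
#' @export
edge_index <- function(frame, params = boundary_params()) {
  if (!is.matrix(frame)) abort("`frame` must be a matrix.", class = "myowave_validation_error")
  if (any(dim(frame) < params$sobel_size)) {
    abort(sprintf("Frame (%d x %d) is smaller than the Sobel aperture (%d).",
                  nrow(frame), ncol(frame), params$sobel_size),
          class = "myowave_size_error")
  }
  s_h <- sobel_response(frame, params$sobel_size, axis = 1)
  s_v <- sobel_response(frame, params$sobel_size, axis = 2)
  s_h + params$vertical_weight * s_v
}

# Sub-pixel refinement of a crossing row: snap to the strongest edge
# response in a small window just inside the crossing, then interpolate the
# peak parabolically from its two neighbours. `direction` is +1 for the
# upper boundary (search downward) and -1 for the lower (search upward).
refine_to_edge_peak <- function(e, rows, direction, reach = 5L) {
  h <- nrow(e)
  nc <- length(rows)
  offs <- direction * (-1L):reach
  win <- outer(rep(1L, length(offs)), rows) + offs      # offsets x columns
  win <- pmin(pmax(win, 1L), h)
  vals <- matrix(e[cbind(as.vector(win), rep(seq_len(nc), each = length(offs)))],
                 nrow = length(offs))
  best <- max.col(t(vals), ties.method = "first")
  peak <- win[cbind(best, seq_len(nc))]
  v0 <- e[cbind(peak, seq_len(nc))]
  vm <- e[cbind(pmax(peak - 1L, 1L), seq_len(nc))]
  vp <- e[cbind(pmin(peak + 1L, h), seq_len(nc))]
  den <- vm - 2 * v0 + vp
  delta <- ifelse(abs(den) > 1e-12, 0.5 * (vm - vp) / den, 0)
  delta <- pmin(pmax(delta, -1), 1)
  peak + delta
}

# raw per-column boundary rows for one edge-index field (0-based rows).
# Coarse stage: the running cumulative sum of |edge index|, normalised by
# the column's mean |edge index| (scale-invariant: multiplying all
# intensities by a constant leaves the profile unchanged), is followed
# top-down and bottom-up; the first/last crossings of the threshold locate
# the boundary's edge response. Refinement stage: each crossing is snapped
# to the sub-pixel peak of the edge response just inside it, cancelling the
# outward bias a tail-crossing estimate would otherwise carry.
detect_frame_boundaries <- function(field, threshold) {
  h <- nrow(field)
  e <- abs(field)
  # soft noise-floor subtraction: the column median |edge| is dominated by
  # background/sensor noise (real edges occupy few rows), so clipping at 3x
  # the median empties the background without touching genuine boundaries;
  # noise-free columns have median 0 and pass through unchanged
  noise_floor <- apply(e, 2, median)
  e <- pmax(sweep(e, 2, 3 * noise_floor, "-"), 0)
  colmean <- colMeans(e)
  ok <- colmean > 0
  upper <- rep(NA_real_, ncol(field))
  lower <- rep(NA_real_, ncol(field))
  if (any(ok)) {
    en <- sweep(e[, ok, drop = FALSE], 2, colmean[ok], "/")
    cs_down <- apply(en, 2, cumsum)
    up1 <- colSums(cs_down <= threshold) + 1L          # first row crossing, 1-based
    cs_up <- apply(en[h:1, , drop = FALSE], 2, cumsum)
    lo1 <- h - colSums(cs_up <= threshold)             # last row crossing, 1-based
    up1[up1 > h] <- NA_integer_
    lo1[lo1 < 1] <- NA_integer_
    eok <- e[, ok, drop = FALSE]
    good_u <- !is.na(up1)
    if (any(good_u)) {
      up1[good_u] <- refine_to_edge_peak(eok[, good_u, drop = FALSE],
                                         up1[good_u], direction = 1L)
    }
    good_l <- !is.na(lo1)
    if (any(good_l)) {
      lo1[good_l] <- refine_to_edge_peak(eok[, good_l, drop = FALSE],
                                         lo1[good_l], direction = -1L)
    }
    upper[ok] <- up1 - 1
    lower[ok] <- lo1 - 1
  }
  valid <- !is.na(upper) & !is.na(lower) & upper < lower
  upper[!valid] <- NA_real_
  lower[!valid] <- NA_real_
  list(upper = upper, lower = lower, valid = valid)
}

#' Detect raw boundaries in a single edge-index field
#'
#' For each column, the absolute edge index is first clipped at 3x the
#' column's median (a robust noise floor; zero for noise-free input), its
#' normalised cumulative sum is followed top-down and bottom-up, the first
#' and last crossings of `params$threshold` locate the boundary edge
#' responses, and each crossing is refined to the sub-pixel peak of its
#' edge response.
#' Columns where no crossing occurs (e.g. outside the organ, where the
#' thin ends yield almost no gradient) are flagged invalid rather than
#' raising an error.
#'
#' @param field An edge-index matrix from [edge_index()].
#' @param params A [boundary_params()].
#'
#' @return A tibble with 0-based `column`, raw `upper` and `lower` rows
#'   (`NA` where invalid) and a logical `valid` flag.
#' @export
detect_boundaries <- function(field, params = boundary_params()) {
  if (!is.matrix(field) || any(!is.finite(field))) {
    abort("`field` must be a finite numeric matrix.", class = "myowave_validation_error")
  }
  raw <- detect_frame_boundaries(field, params$threshold)
  tibble(
    column = seq_len(ncol(field)) - 1L,
    upper = raw$upper, lower = raw$lower, valid = raw$valid
  )
}

# spline-smooth one frame's raw boundaries; returns upper/lower/valid
smooth_frame_boundaries <- function(upper, lower, valid, knot_spacing, height) {
  n <- length(upper)
  out <- list(upper = rep(NA_real_, n), lower = rep(NA_real_, n),
              valid = rep(FALSE, n))
  vs <- which(valid)
  if (length(vs) < 4) return(out)
  # merge valid runs separated by bridgeable gaps; keep the widest segment
  splits <- which(diff(vs) > knot_spacing + 1L)
  seg_start <- c(1L, splits + 1L)
  seg_end <- c(splits, length(vs))
  spans <- vs[seg_end] - vs[seg_start]
  k <- which.max(spans)
  seg <- vs[seg_start[k]]:vs[seg_end[k]]
  knot_pool <- vs[seg_start[k]:seg_end[k]]
  if (length(knot_pool) < 4) return(out)
  idx <- unique(c(seq(1L, length(knot_pool), by = knot_spacing), length(knot_pool)))
  knots <- knot_pool[idx]
  if (length(knots) < 4) knots <- knot_pool
  x <- knots - 1                    # 0-based column coordinate
  xs <- seg - 1
  up <- splinefun(x, upper[knots], method = "fmm")(xs)
  lo <- splinefun(x, lower[knots], method = "fmm")(xs)
  up <- pmin(pmax(up, 0), height - 1)
  lo <- pmin(pmax(lo, 0), height - 1)
  crossed <- up >= lo
  if (any(crossed)) {
    mid <- (up[crossed] + lo[crossed]) / 2
    up[crossed] <- pmax(mid - 0.5, 0)
    lo[crossed] <- pmin(mid + 0.5, height - 1)
  }
  out$upper[seg] <- up
  out$lower[seg] <- lo
  out$valid[seg] <- TRUE
  out
}

#' Smooth raw boundaries with a knotted cubic spline
#'
#' Fits a cubic interpolation spline through knot columns spaced every
#' `knot_spacing` valid columns of each frame and evaluates it over the
#' frame's main valid run, correcting abrupt single-column excursions
#' (e.g. from stain artifacts near the organ edge). Interior invalid gaps
#' up to `knot_spacing` columns wide are bridged; the invalid runs at the
#' thin organ ends are left invalid. Where smoothing would make the upper
#' boundary cross the lower, both are clamped to their midpoint +/- 0.5 px
#' so the per-column area stays non-negative. Frames with fewer than 4
#' valid knot columns are flagged entirely unusable.
#'
#' @param raw A tibble of raw boundaries with columns `frame` (optional for
#'   a single frame), `column`, `upper`, `lower`, `valid`, as from
#'   [detect_boundaries()].
#' @param params A [boundary_params()].
#' @param height Frame height in pixels (for clamping).
#'
#' @return A tibble `frame, column, upper, lower, valid` with fractional
#'   smoothed boundary rows.
#' @export
smooth_boundaries <- function(raw, params = boundary_params(), height = Inf) {
  if (!("frame" %in% names(raw))) raw$frame <- 0L
  check_columns(raw, c("frame", "column", "upper", "lower", "valid"), "Raw boundary")
  raw |>
    group_by(.data$frame) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$column)
      sm <- smooth_frame_boundaries(df$upper, df$lower, df$valid,
                                    params$knot_spacing, height)
      tibble(column = df$column, upper = sm$upper, lower = sm$lower, valid = sm$valid)
    }) |>
    ungroup()
}

#' Trace organ boundaries through a whole recording
#'
#' Runs the full boundary-identification step: Gaussian pre-smoothing of
#' the stack, the weighted Sobel edge index per frame, cumulative-sum
#' crossing detection per column, and cubic-spline regularisation of the
#' raw boundaries.
#'
#' @param stack A [frame_stack()] (raw; smoothing is internal).
#' @param params A [boundary_params()].
#'
#' @return A tibble `frame, column, upper, lower, valid` with 0-based
#'   frame/column indices and fractional boundary rows.
#' @examples
#' sim <- simulate_video(sim_params(width = 200, height = 60, duration_s = 10))
#' b <- trace_boundaries(sim$stack)
#' head(b)
#' @export
trace_boundaries <- function(stack, params = boundary_params()) {
  sm <- smooth_stack(stack, params)
  h <- stack_height(stack)
  nt <- n_frames(stack)
  res <- vector("list", nt)
  for (t in seq_len(nt)) {
    field <- edge_index(sm$frames[, , t], params)
    raw <- detect_frame_boundaries(field, params$threshold)
    smf <- smooth_frame_boundaries(raw$upper, raw$lower, raw$valid,
                                   params$knot_spacing, h)
    res[[t]] <- tibble(
      frame = t - 1L,
      column = seq_len(stack_width(stack)) - 1L,
      upper = smf$upper, lower = smf$lower, valid = smf$valid
    )
  }
  bind_rows(res)
}
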