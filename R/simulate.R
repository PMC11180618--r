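#' Synthetic contracting-tube video parameters
#'
#' Describes a horizontally pinned bright tube on a dark background with
#' travelling constriction waves — the synthetic stand-in for an ex vivo
#' uterine-horn recording. Defaults reproduce the acquisition conditions
#' the package targets: 5 frames/s, 110.85 px/mm, a 300 s recording, and
#' waves at the scale reported for spontaneous uterine contractions
#' (12.8 um/s speed, 800 um crest-to-crest spacing, 190 um band width).
#'
#' Two contraction modes are simulated. In `"circular"` mode a wave locally
#' narrows the tube: half-diameter `r(x,t) = r0 * (1 - a * w(x - s v t))`
#' where `w` is a raised-cosine bump train of compact support `band_width`
#' and spacing `wave_spacing`, and interior intensity rises as
#' `I0 * (r0 / r)^gamma` (fluorophore conservation: compressed tissue is
#' brighter). In `"longitudinal"` mode the diameter stays fixed and only a
#' density wave travels: `I = I0 * (1 + a * w)^gamma`. Ends are tapered to
#' mimic the thin, low-gradient horn extremities; optional stain-like
#' blobs outside the tube mimic dish artifacts; Gaussian noise and 8-bit
#' quantisation mimic the camera.
#'
#' @param width,height Frame size in pixels.
#' @param duration_s Recording length in seconds.
#' @param fps Frames per second.
#' @param px_per_mm Pixels per millimetre.
#' @param r0 Relaxed tube half-diameter in pixels; `2 * r0` must be below
#'   80% of the frame height.
#' @param wave_speed_um_s Wave speed v* (um/s).
#' @param wave_spacing_um Crest-to-crest spacing lambda* (um).
#' @param band_width_um Spatial extent w* of one constriction (um); must be
#'   smaller than the spacing.
#' @param constriction_fraction Relative depth a of the constriction,
#'   in (0, 1).
#' @param direction `"toward_cervix"` (rightward on the oviduct-left axis)
#'   or `"toward_oviduct"`.
#' @param mode `"circular"` or `"longitudinal"`.
#' @param gamma Intensity-conservation exponent.
#' @param noise_sd Gaussian noise standard deviation on the 8-bit scale.
#' @param artifact_count Number of static bright blobs outside the tube.
#' @param taper_fraction Fraction of the width over which each end thins
#'   out.
#' @param base_intensity Interior intensity I0 of the relaxed tube (8-bit).
#' @param seed Integer seed driving all randomness (noise, artifacts).
#'
#' @return A `sim_params` object.
#' @export
sim_params <- function(width = 1200, height = 160, duration_s = 300, fps = 5,
                       px_per_mm = 110.85, r0 = 40,
                       wave_speed_um_s = 12.8, wave_spacing_um = 800,
                       band_width_um = 190, constriction_fraction = 0.3,
                       direction = c("toward_cervix", "toward_oviduct"),
                       mode = c("circular", "longitudinal"),
                       gamma = 1, noise_sd = 0, artifact_count = 0,
                       taper_fraction = 0.08, base_intensity = 140, seed = 1) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  num_pos <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      abort(sprintf("`%s` must be a single positive number.", name),
            class = "myowave_validation_error")
    }
  }
  for (nm in c("width", "height", "duration_s", "fps", "px_per_mm", "r0",
               "wave_spacing_um", "band_width_um", "base_intensity")) {
    num_pos(get(nm), nm)
  }
  if (wave_speed_um_s < 0) {
    abort("`wave_speed_um_s` must be non-negative.", class = "myowave_validation_error")
  }
  if (constriction_fraction < 0 || constriction_fraction >= 1) {
    abort("`constriction_fraction` must lie in [0, 1).", class = "myowave_validation_error")
  }
  if (band_width_um >= wave_spacing_um) {
    abort("`band_width_um` must be smaller than `wave_spacing_um`.",
          class = "myowave_validation_error")
  }
  if (2 * r0 >= 0.8 * height) {
    abort("Tube does not fit: 2 * r0 must be below 80% of the frame height.",
          class = "myowave_geometry_error")
  }
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      duration_s = duration_s, fps = fps, px_per_mm = px_per_mm, r0 = r0,
      wave_speed_um_s = wave_speed_um_s, wave_spacing_um = wave_spacing_um,
      band_width_um = band_width_um, constriction_fraction = constriction_fraction,
      direction = direction, mode = mode, gamma = gamma, noise_sd = noise_sd,
      artifact_count = as.integer(artifact_count), taper_fraction = taper_fraction,
      base_intensity = base_intensity, seed = as.integer(seed)
    ),
    class = "myowave_sim_params"
  )
}

# raised-cosine bump train: 1 at crest centres, 0 outside compact support
bump_train <- function(u, lambda_px, w_px) {
  d <- u %% lambda_px
  d <- pmin(d, lambda_px - d)
  ifelse(d <= w_px / 2, 0.5 * (1 + cos(2 * pi * d / w_px)), 0)
}

# smoothstep taper from thin ends to full diameter
taper_profile <- function(width, taper_fraction, floor_value = 0.15) {
  x <- seq_len(width) - 1L
  n_t <- max(round(taper_fraction * width), 1L)
  u <- pmin(pmin(x, width - 1L - x) / n_t, 1)
  floor_value + (1 - floor_value) * (3 * u^2 - 2 * u^3)
}

#' Simulate a contracting-tube video with ground truth
#'
#' Renders the tube described by [sim_params()] frame by frame and returns
#' the stack together with a `ground_truth` object from which exact wave
#' annotations can be drawn with [truth_annotations()]. All randomness
#' derives from `params$seed`; the same parameters always yield an
#' identical stack.
#'
#' @param params A [sim_params()].
#' @param render If `FALSE`, skip rendering and return only the ground
#'   truth (useful when downstream work needs annotations, not pixels).
#'
#' @return A list with `stack` (a [frame_stack()], or `NULL` when
#'   `render = FALSE`) and `truth` (a `ground_truth` object).
#' @examples
#' sim <- simulate_video(sim_params(width = 300, height = 60, duration_s = 20))
#' sim$stack
#' sim$truth$frequency_hz
#' @export
simulate_video <- function(params, render = TRUE) {
  stopifnot(inherits(params, "myowave_sim_params"))
  p <- params
  px_per_um <- p$px_per_mm / 1000
  lambda_px <- p$wave_spacing_um * px_per_um
  w_px <- p$band_width_um * px_per_um
  s <- if (p$direction == "toward_cervix") 1 else -1
  v_px_frame <- p$wave_speed_um_s * px_per_um / p$fps * s
  n_t <- as.integer(round(p$duration_s * p$fps))
  if (n_t < 2) abort("Simulation must span at least 2 frames.",
                     class = "myowave_validation_error")
  phase0 <- lambda_px / 2
  cy <- (p$height - 1) / 2
  truth <- structure(
    list(
      params = p, n_frames = n_t, lambda_px = lambda_px, w_px = w_px,
      v_px_frame = v_px_frame, phase0 = phase0, center_row = cy,
      velocity_um_s = p$wave_speed_um_s, spacing_um = p$wave_spacing_um,
      band_width_um = p$band_width_um,
      constriction = p$constriction_fraction,
      frequency_hz = p$wave_speed_um_s / p$wave_spacing_um
    ),
    class = "myowave_ground_truth"
  )
  if (!render) return(list(stack = NULL, truth = truth))

  x <- seq_len(p$width) - 1L
  taper <- taper_profile(p$width, p$taper_fraction)
  rowdist <- abs(seq_len(p$height) - 1L - cy)
  frames <- array(0, dim = c(p$height, p$width, n_t))
  with_local_seed(p$seed, {
    artifacts <- matrix(0, p$height, p$width)
    if (p$artifact_count > 0) {
      for (i in seq_len(p$artifact_count)) {
        # stain-like blob strictly outside the tube
        repeat {
          ar <- runif(1, 0, p$height - 1)
          if (abs(ar - cy) > p$r0 + 8) break
        }
        ac <- runif(1, 0, p$width - 1)
        blob <- exp(-((rowdist - abs(ar - cy))^2) / 8) %o% exp(-((x - ac)^2) / 8)
        artifacts <- artifacts + 180 * blob
      }
    }
    for (t in seq_len(n_t)) {
      u <- x - phase0 - v_px_frame * (t - 1L)
      wv <- bump_train(u, lambda_px, w_px)
      if (p$mode == "circular") {
        r_wave <- p$r0 * (1 - p$constriction_fraction * wv)
        intensity <- p$base_intensity * (p$r0 / r_wave)^p$gamma
      } else {
        r_wave <- rep(p$r0, p$width)
        intensity <- p$base_intensity * (1 + p$constriction_fraction * wv)^p$gamma
      }
      r <- r_wave * taper
      inten <- intensity * taper
      cover <- pmin(pmax(outer(-rowdist, r, "+") + 0.5, 0), 1)
      fr <- cover * rep(inten, each = p$height) + artifacts
      if (p$noise_sd > 0) {
        fr <- fr + matrix(rnorm(length(fr), sd = p$noise_sd), nrow = p$height)
      }
      frames[, , t] <- pmin(pmax(round(fr), 0), 255)
    }
  })
  list(stack = frame_stack(frames, frame_interval = 1 / p$fps), truth = truth)
}

#' @export
print.myowave_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %s %s waves: v = %g um/s, spacing = %g um, band = %g um, f = %g Hz\n",
    x$params$mode, x$params$direction, x$velocity_um_s, x$spacing_um,
    x$band_width_um, x$frequency_hz
  ))
  invisible(x)
}

# true column of crest k at (0-based) frame t
crest_column <- function(truth, k, t) {
  truth$phase0 + k * truth$lambda_px + truth$v_px_frame * t
}

#' Ground-truth geometry helpers
#'
#' `crest_columns_at()` returns the true crest-centre columns inside the
#' frame at one time point. `true_boundaries()` returns the analytic upper
#' and lower tube boundaries for every frame and column, for measuring
#' boundary-tracing error. `crest_contrast()` quantifies how strongly a
#' spatiotemporal map displays ridges where the true waves pass: cells
#' within `tol` columns of a true crest are "signal", the remaining
#' interior cells are "background", and the function reports the mean
#' signal excess over background in units of the background standard
#' deviation.
#'
#' @param truth A `ground_truth` from [simulate_video()].
#' @param t 0-based frame index.
#' @param map An [st_map()] computed from the simulated video.
#' @param tol Column tolerance around a true crest centre defining the
#'   signal band; defaults to half the true band width plus 2 columns, so
#'   the band's flanking change ridges are included.
#' @param margin Interior margin (columns) excluded at both ends, where
#'   the taper and detrend-window edge effects live. Default 60.
#'
#' @return `crest_columns_at()`: numeric vector of columns.
#'   `true_boundaries()`: tibble `frame, column, upper, lower`.
#'   `crest_contrast()`: list with `signal`, `noise_sd` and their `ratio`.
#' @export
crest_columns_at <- function(truth, t) {
  p <- truth$params
  k_range <- seq(floor((0 - truth$phase0 - truth$v_px_frame * t) / truth$lambda_px) - 1,
                 ceiling((p$width - truth$phase0 - truth$v_px_frame * t) / truth$lambda_px) + 1)
  cols <- truth$phase0 + k_range * truth$lambda_px + truth$v_px_frame * t
  cols[cols >= 0 & cols <= p$width - 1]
}

#' @rdname crest_columns_at
#' @export
true_boundaries <- function(truth) {
  p <- truth$params
  x <- seq_len(p$width) - 1L
  taper <- taper_profile(p$width, p$taper_fraction)
  purrr::map_dfr(seq_len(truth$n_frames) - 1L, function(t) {
    wv <- bump_train(x - truth$phase0 - truth$v_px_frame * t, truth$lambda_px, truth$w_px)
    r_wave <- if (p$mode == "circular") {
      p$r0 * (1 - p$constriction_fraction * wv)
    } else {
      rep(p$r0, p$width)
    }
    r <- r_wave * taper
    tibble(frame = t, column = x,
           upper = truth$center_row - r, lower = truth$center_row + r)
  })
}

#' @rdname crest_columns_at
#' @export
crest_contrast <- function(map, truth, tol = NULL, margin = 60) {
  stopifnot(inherits(map, "myowave_st_map"), inherits(truth, "myowave_ground_truth"))
  tol <- tol %||% (truth$w_px / 2 + 2)
  v <- map$values
  nc <- nrow(v); nt <- ncol(v)
  interior <- seq_len(nc) - 1L
  interior <- interior[interior >= margin & interior < nc - margin]
  sig_vals <- numeric(0); bg_vals <- numeric(0)
  for (t in seq_len(nt) - 1L) {
    crests <- crest_columns_at(truth, t)
    col_vals <- v[interior + 1L, t + 1L]
    if (length(crests) == 0) next
    d <- vapply(interior, function(cc) min(abs(cc - crests)), numeric(1))
    sig_vals <- c(sig_vals, col_vals[d <= tol])
    bg_vals <- c(bg_vals, col_vals[d > tol + 5])
  }
  signal <- mean(sig_vals, na.rm = TRUE) - mean(bg_vals, na.rm = TRUE)
  noise_sd <- stats::sd(bg_vals, na.rm = TRUE)
  list(signal = signal, noise_sd = noise_sd, ratio = signal / noise_sd)
}

#' Exact wave annotations from simulation ground truth
#'
#' Builds [compute_metrics()]-ready annotations whose ridge endpoints lie
#' exactly on true crest trajectories, whose band extent equals the true
#' band width, and whose successor-crest frame follows from the true
#' spacing and speed. Only crests whose trajectory stays inside the frame
#' (with a half-band margin) are eligible; an error is raised when fewer
#' than `n_waves` qualify.
#'
#' @param truth A `ground_truth` from [simulate_video()].
#' @param n_waves Number of annotations to draw; `NULL` returns every
#'   eligible crest.
#' @param seed Integer seed for the uniform crest sample; `NULL` takes the
#'   first `n_waves` eligible crests deterministically.
#'
#' @return An annotation tibble (see [compute_metrics()]) with a
#'   `true_crest` column identifying the sampled crest.
#' @export
truth_annotations <- function(truth, n_waves = NULL, seed = NULL) {
  stopifnot(inherits(truth, "myowave_ground_truth"))
  p <- truth$params
  n_t <- truth$n_frames
  margin <- truth$w_px / 2 + 2
  lo <- margin
  hi <- p$width - 1 - margin
  ks <- seq(floor((lo - truth$phase0 - abs(truth$v_px_frame) * n_t) / truth$lambda_px) - 1,
            ceiling((hi - truth$phase0 + abs(truth$v_px_frame) * n_t) / truth$lambda_px) + 1)
  rows <- purrr::map_dfr(ks, function(k) {
    c_start <- crest_column(truth, k, 0)
    c_end <- crest_column(truth, k, n_t - 1)
    # frames during which the crest is safely inside the frame
    if (truth$v_px_frame == 0) {
      if (c_start < lo || c_start > hi) return(NULL)
      t0 <- 0; t1 <- n_t - 1
    } else {
      tt <- sort(c((lo - truth$phase0 - k * truth$lambda_px) / truth$v_px_frame,
                   (hi - truth$phase0 - k * truth$lambda_px) / truth$v_px_frame))
      t0 <- max(ceiling(tt[1]), 0)
      t1 <- min(floor(tt[2]), n_t - 1)
      if (t1 - t0 < 1) return(NULL)
      # a marked ridge covers a local stretch of the crest line (about one
      # wave spacing), not the crest's entire traversal of the organ
      span_frames <- ceiling(max(truth$lambda_px, 40) / abs(truth$v_px_frame))
      t1 <- min(t1, t0 + span_frames)
    }
    ridge_c0 <- crest_column(truth, k, t0)
    ridge_c1 <- crest_column(truth, k, t1)
    next_t <- if (truth$v_px_frame == 0) {
      NA_real_
    } else {
      t0 + truth$lambda_px / abs(truth$v_px_frame)
    }
    if (!is.na(next_t) && next_t > n_t - 1) next_t <- NA_real_
    tibble(
      map_id = sprintf("sim-seed%d", p$seed),
      ridge_c0 = ridge_c0, ridge_t0 = t0,
      ridge_c1 = ridge_c1, ridge_t1 = t1,
      band_c0 = ridge_c0 - truth$w_px / 2,
      band_c1 = ridge_c0 + truth$w_px / 2,
      next_ridge_t = next_t,
      true_crest = k
    )
  })
  if (is.null(n_waves)) n_waves <- nrow(rows)
  if (nrow(rows) < n_waves || n_waves == 0) {
    abort(sprintf("Only %d crest(s) eligible but %d annotation(s) requested.",
                  nrow(rows), max(n_waves, 1)),
          class = "myowave_validation_error")
  }
  if (is.null(seed)) {
    rows[seq_len(n_waves), , drop = FALSE]
  } else {
    with_local_seed(seed, rows[sort(sample.int(nrow(rows), n_waves)), , drop = FALSE])
  }
}
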