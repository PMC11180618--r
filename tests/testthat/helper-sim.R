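# Small simulated recordings shared across test files. Sizes are kept well
# below the acquisition scale so each file runs in seconds; the acceptance
# tests exercise the full-scale conditions.

quick_sim <- function(width = 400, height = 80, duration_s = 40, r0 = 20,
                      wave_speed_um_s = 40, wave_spacing_um = 800,
                      band_width_um = 190, ...) {
  simulate_video(sim_params(
    width = width, height = height, duration_s = duration_s, r0 = r0,
    wave_speed_um_s = wave_speed_um_s, wave_spacing_um = wave_spacing_um,
    band_width_um = band_width_um, ...
  ))
}

# mean absolute boundary error against the analytic tube geometry,
# over valid interior columns (the tapered ends are excluded)
boundary_mae <- function(boundaries, truth, margin = NULL) {
  p <- truth$params
  if (is.null(margin)) margin <- round(p$taper_fraction * p$width) + 10
  tb <- true_boundaries(truth)
  keep <- boundaries[boundaries$valid &
                       boundaries$column >= margin &
                       boundaries$column < p$width - margin, ]
  j <- dplyr::inner_join(keep, tb, by = c("frame", "column"), suffix = c("", "_true"))
  mean(abs(j$upper - j$upper_true) + abs(j$lower - j$lower_true)) / 2
}

# one bright-band test frame: rows band_rows at value `level`, rest 0
band_frame <- function(height = 100, width = 60, band_rows = 41:61, level = 200) {
  m <- matrix(0, height, width)
  m[band_rows, ] <- level
  m
}
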