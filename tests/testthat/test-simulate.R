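test_that("simulation parameters validate geometry and wave consistency", {
  expect_error(sim_params(height = 80, r0 = 35), class = "myowave_geometry_error")
  expect_error(sim_params(band_width_um = 900, wave_spacing_um = 800),
               class = "myowave_validation_error")
  expect_error(sim_params(constriction_fraction = 1), class = "myowave_validation_error")
})

test_that("rendering is deterministic and 8-bit quantised", {
  p <- sim_params(width = 200, height = 60, duration_s = 6, r0 = 15,
                  noise_sd = 4, artifact_count = 2, seed = 42)
  s1 <- simulate_video(p)$stack
  s2 <- simulate_video(p)$stack
  expect_identical(s1$frames, s2$frames)
  expect_true(all(s1$frames == round(s1$frames)))
  expect_true(all(s1$frames >= 0 & s1$frames <= 255))

  s3 <- simulate_video(sim_params(width = 200, height = 60, duration_s = 6,
                                  r0 = 15, noise_sd = 4, seed = 43))$stack
  expect_false(identical(s1$frames, s3$frames))
})

test_that("a wave-free tube yields a constant interior area map", {
  sim <- quick_sim(width = 300, height = 60, duration_s = 8, r0 = 15,
                   constriction_fraction = 0)
  b <- trace_boundaries(sim$stack)
  area <- column_area(b)
  interior <- area$values[60:240, ]
  expect_lt(max(interior, na.rm = TRUE) - min(interior, na.rm = TRUE), 2)
  expect_equal(mean(interior, na.rm = TRUE), 2 * 15, tolerance = 0.1)
})

test_that("circular waves depress the tube diameter to 2 r0 (1 - a)", {
  sim <- quick_sim(width = 400, height = 100, duration_s = 20, r0 = 30,
                   wave_speed_um_s = 40, constriction_fraction = 0.3)
  b <- trace_boundaries(sim$stack)
  area <- column_area(b)
  interior <- area$values[60:340, ]
  expect_equal(min(interior, na.rm = TRUE), 2 * 30 * 0.7, tolerance = 2 / 42)
})

test_that("compression conserves the per-column fluorophore proxy at gamma 1", {
  sim <- quick_sim(width = 400, height = 100, duration_s = 20, r0 = 30,
                   wave_speed_um_s = 40, gamma = 1)
  # total fluorophore in a column = column intensity sum (area x mean
  # intensity, free of row-window discretisation); background is zero
  proxy <- apply(sim$stack$frames, 3, colSums)      # columns x frames
  interior <- 60:340
  drift <- apply(proxy[interior, ], 1, function(row) diff(range(row)) / mean(row))
  expect_lt(median(drift), 0.02)
  expect_lt(max(drift), 0.05)
})

test_that("constricted columns are brighter than relaxed ones in the same frame", {
  sim <- quick_sim(width = 400, height = 100, duration_s = 10, r0 = 30,
                   wave_speed_um_s = 40, gamma = 1)
  tb <- true_boundaries(sim$truth) |> dplyr::mutate(valid = TRUE)
  inten <- column_mean_intensity(sim$stack, tb)
  crests <- round(crest_columns_at(sim$truth, 0))
  crests <- crests[crests > 60 & crests < 340]
  relaxed <- setdiff(100:300, as.vector(outer(crests, -30:30, "+")))
  expect_gt(min(inten$values[crests + 1, 1]), max(inten$values[relaxed + 1, 1]))
})

test_that("longitudinal waves show in intensity but not in area", {
  p <- sim_params(width = 500, height = 80, duration_s = 30, r0 = 20,
                  wave_speed_um_s = 60, mode = "longitudinal", noise_sd = 5,
                  seed = 9)
  sim <- simulate_video(p)
  res <- run_pipeline(sim$stack)
  cc_area <- crest_contrast(res$enhanced_area, sim$truth)
  cc_int <- crest_contrast(res$enhanced_intensity, sim$truth)
  expect_lt(cc_area$ratio, 3)
  expect_gt(cc_int$ratio, 3)
})

test_that("truth annotations propagate speed, spacing and direction exactly", {
  sim <- simulate_video(sim_params(width = 900, height = 80, duration_s = 300,
                                   r0 = 20), render = FALSE)
  expect_equal(sim$truth$frequency_hz, 12.8 / 800)
  ann <- truth_annotations(sim$truth, n_waves = 4, seed = 3)
  m <- compute_metrics(ann, calibration())
  expect_equal(m$frequency_hz[!is.na(m$frequency_hz)],
               rep(0.016, sum(!is.na(m$frequency_hz))))
  expect_true(all(m$direction == "toward_cervix"))

  rev_sim <- simulate_video(sim_params(width = 900, height = 80, duration_s = 300,
                                       r0 = 20, direction = "toward_oviduct"),
                            render = FALSE)
  rev_ann <- truth_annotations(rev_sim$truth, n_waves = 4, seed = 3)
  rev_m <- compute_metrics(rev_ann, calibration())
  expect_true(all(rev_m$direction == "toward_oviduct"))

  expect_error(truth_annotations(sim$truth, n_waves = 500),
               class = "myowave_validation_error")
})
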