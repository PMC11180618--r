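ann_row <- function(c0 = 0, t0 = 0, c1 = 111, t1 = 50, b0 = 100, b1 = 121,
                    nxt = NA_real_, id = "m") {
  tibble::tibble(map_id = id, ridge_c0 = c0, ridge_t0 = t0, ridge_c1 = c1,
                 ridge_t1 = t1, band_c0 = b0, band_c1 = b1, next_ridge_t = nxt)
}

test_that("pixel and frame conversions match the acquisition calibration", {
  cal <- calibration()
  expect_equal(px_to_mm(110.85, cal), 1)
  expect_equal(frames_to_s(1500, cal), 300)
  expect_equal(px_to_mm(0, cal), 0)
  expect_equal(px_to_mm(221.7, calibration(px_per_mm = 110.85)), 2)
})

test_that("ridge slope yields velocity and direction; band extent yields amplitude", {
  m <- compute_metrics(ann_row(), calibration())
  expect_equal(m$velocity_um_s, (111 / 110.85) / 10 * 1000, tolerance = 1e-12)
  expect_equal(m$direction, "toward_cervix")
  expect_equal(m$amplitude_um, 21 / 110.85 * 1000)
  expect_true(is.na(m$period_s) && is.na(m$frequency_hz) && is.na(m$wavelength_um))

  flat <- compute_metrics(ann_row(c1 = 0), calibration())
  expect_equal(flat$velocity_um_s, 0)
  expect_equal(flat$direction, "stationary")

  leftward <- compute_metrics(ann_row(c0 = 200, c1 = 100), calibration())
  expect_equal(leftward$direction, "toward_oviduct")
})

test_that("period, frequency and wavelength follow the definitional chain", {
  # successor crest 312.5 frames later at 5 fps -> 62.5 s period, 0.016 Hz
  m <- compute_metrics(ann_row(c0 = 0, t0 = 0, c1 = 88.68, t1 = 625, nxt = 312.5),
                       calibration())
  expect_equal(m$period_s, 62.5)
  expect_equal(m$frequency_hz, 0.016)
  expect_equal(m$velocity_um_s, 88.68 / 110.85 * 1000 / 125, tolerance = 1e-12)
  # a 12.8 um/s wave at 0.016 Hz spans 800 um
  expect_equal(12.8 / 0.016, 800)
  expect_equal(m$wavelength_um, m$velocity_um_s / m$frequency_hz)
})

test_that("wavelength equals velocity times period to machine precision", {
  withr::with_seed(42, {
    n <- 200
    ann <- tibble::tibble(
      map_id = "p",
      ridge_c0 = runif(n, 0, 500), ridge_t0 = runif(n, 0, 500),
      ridge_c1 = runif(n, 0, 500), ridge_t1 = NA_real_,
      band_c0 = runif(n, 0, 500), band_c1 = runif(n, 0, 500),
      next_ridge_t = NA_real_
    )
    ann$ridge_t1 <- ann$ridge_t0 + runif(n, 1, 300)
    ann$next_ridge_t <- ann$ridge_t0 + runif(n, 1, 500)
    m <- compute_metrics(ann, calibration(fps = 5, px_per_mm = 110.85))
    expect_equal(m$wavelength_um, m$velocity_um_s * m$period_s, tolerance = 1e-14)
    expect_equal(m$frequency_hz * m$period_s, rep(1, n), tolerance = 1e-15)
    expect_true(all(m$velocity_um_s >= 0 & m$amplitude_um >= 0))
  })
})

test_that("mirroring the spatial axis flips direction but no magnitude", {
  n_col <- 600
  ann <- ann_row(c0 = 50, c1 = 180, nxt = 100)
  flipped <- ann_row(c0 = n_col - 1 - 50, c1 = n_col - 1 - 180, nxt = 100)
  m1 <- compute_metrics(ann, calibration())
  m2 <- compute_metrics(flipped, calibration())
  expect_equal(m1$velocity_um_s, m2$velocity_um_s)
  expect_equal(m1$amplitude_um, m2$amplitude_um)
  expect_equal(m1$period_s, m2$period_s)
  expect_equal(m1$direction, "toward_cervix")
  expect_equal(m2$direction, "toward_oviduct")
})

test_that("degenerate annotations are rejected", {
  expect_error(compute_metrics(ann_row(t1 = 0), calibration()),
               class = "myowave_validation_error")
  expect_error(compute_metrics(ann_row(nxt = -5), calibration()),
               class = "myowave_validation_error")
  expect_error(compute_metrics(ann_row()[0, ], calibration()),
               class = "myowave_validation_error")
})

test_that("summaries report per-metric medians and counts", {
  cal <- calibration()
  one <- compute_metrics(ann_row(nxt = 100), cal)
  s1 <- summarize_metrics(one)
  expect_equal(s1$median[s1$metric == "velocity_um_s"], one$velocity_um_s)

  ann3 <- dplyr::bind_rows(
    ann_row(c0 = 0, c1 = 11.085, t1 = 100),   # 10 um/s over 20 s
    ann_row(c0 = 0, c1 = 22.17, t1 = 100),
    ann_row(c0 = 0, c1 = 33.255, t1 = 100)
  )
  m3 <- compute_metrics(ann3, cal)
  s3 <- summarize_metrics(m3)
  expect_equal(s3$median[s3$metric == "velocity_um_s"], 10, tolerance = 1e-9)
  expect_equal(s3$n[s3$metric == "period_s"], 0)
  # order invariance
  s3r <- summarize_metrics(m3[3:1, ])
  expect_equal(s3, s3r)
  expect_error(summarize_metrics(m3[0, ]), class = "myowave_validation_error")
})

test_that("truth annotations recover the simulated wave parameters", {
  sim <- simulate_video(sim_params(width = 900, height = 80, duration_s = 300,
                                   r0 = 20, wave_speed_um_s = 12.8,
                                   wave_spacing_um = 800, band_width_um = 190),
                        render = FALSE)
  ann <- truth_annotations(sim$truth, n_waves = 6, seed = 2)
  m <- compute_metrics(ann, calibration())
  expect_equal(median(m$velocity_um_s), 12.8, tolerance = 0.05)
  expect_equal(median(m$frequency_hz, na.rm = TRUE), 12.8 / 800, tolerance = 0.05)
  expect_equal(median(m$amplitude_um), 190, tolerance = 0.05)
})
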