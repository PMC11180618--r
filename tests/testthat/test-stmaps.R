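make_boundaries <- function(upper, lower, valid = TRUE, n_frames = 2) {
  nc <- length(upper)
  tidyr::expand_grid(frame = 0:(n_frames - 1), column = 0:(nc - 1)) |>
    dplyr::mutate(upper = rep(upper, n_frames), lower = rep(lower, n_frames),
                  valid = rep(valid, length.out = nc * n_frames))
}

test_that("column area is the boundary distance, with masks propagated", {
  b <- make_boundaries(upper = rep(40, 10), lower = rep(60, 10))
  m <- column_area(b)
  expect_equal(m$values, matrix(20, 10, 2), ignore_attr = TRUE)

  b2 <- make_boundaries(upper = rep(40, 10), lower = rep(60, 10),
                        valid = c(rep(FALSE, 3), rep(TRUE, 7)))
  m2 <- column_area(b2)
  expect_true(all(is.na(m2$values[1:3, ])))
  expect_true(all(!is.na(m2$values[4:10, ])))

  # degenerate (upper == lower) columns are masked, not zero-valued
  b3 <- make_boundaries(upper = c(50, rep(40, 9)), lower = c(50, rep(60, 9)))
  expect_true(all(is.na(column_area(b3)$values[1, ])))
})

test_that("orientation flips the spatial axis so it runs oviduct to cervix", {
  b <- make_boundaries(upper = rep(10, 6), lower = 20 + (0:5))
  left <- column_area(b, calibration(orientation = "left"))
  right <- column_area(b, calibration(orientation = "right"))
  expect_equal(right$values, left$values[6:1, ], ignore_attr = TRUE)
})

test_that("column mean intensity averages raw pixels between the boundaries", {
  fs <- frame_stack(array(100, c(50, 8, 2)), 0.2)
  b <- make_boundaries(upper = rep(10, 8), lower = rep(30, 8))
  m <- column_mean_intensity(fs, b)
  expect_equal(m$values, matrix(100, 8, 2), ignore_attr = TRUE)

  # pushing the boundaries into dark background lowers the mean, monotonically
  arr <- array(0, c(60, 8, 2))
  arr[21:41, , ] <- 200
  fs2 <- frame_stack(arr, 0.2)
  means <- sapply(c(0, 5, 10), function(off) {
    bb <- make_boundaries(upper = rep(20 - off, 8), lower = rep(40 + off, 8))
    column_mean_intensity(fs2, bb)$values[1, 1]
  })
  expect_true(all(diff(means) < 0))

  # invalid columns stay masked
  b3 <- make_boundaries(upper = rep(10, 8), lower = rep(30, 8),
                        valid = c(FALSE, rep(TRUE, 7)))
  expect_true(all(is.na(column_mean_intensity(fs, b3)$values[1, ])))
})

test_that("enhancement flattens constants and is immune to smooth spatial trends", {
  cal <- calibration()
  const <- st_map(matrix(37, 80, 40), "mean_intensity", cal)
  e <- enhance_map(const, enhance_params(spatial_detrend_window = 21,
                                         temporal_lowpass_window = 5))
  expect_equal(max(abs(e$values)), 0, tolerance = 1e-10)

  base <- matrix(rnorm(120 * 60, sd = 1), 120, 60)
  slow <- matrix(rep(5 * sin((0:119) / 600 * 2 * pi), 60), 120, 60)  # period >> window
  p <- enhance_params(spatial_detrend_window = 31, temporal_lowpass_window = 5)
  e1 <- enhance_map(st_map(base, "mean_intensity", cal), p)
  e2 <- enhance_map(st_map(base + slow, "mean_intensity", cal), p)
  # compare away from the ends, where the detrend window is truncated
  core <- 32:88
  rel_rms <- sqrt(mean((e2$values[core, ] - e1$values[core, ])^2)) /
    sqrt(mean(e1$values[core, ]^2))
  expect_lt(rel_rms, 0.02)
})

test_that("enhanced ridges travel at the input slope", {
  # diagonal ridge moving v columns per frame through a noisy background
  v <- 1.5
  nc <- 200; nt <- 90
  m <- matrix(0, nc, nt)
  for (t in 0:(nt - 1)) {
    centre <- 30 + v * t
    cols <- 0:(nc - 1)
    m[, t + 1] <- 40 * exp(-((cols - centre)^2) / 50)
  }
  e <- enhance_map(st_map(m, "mean_intensity", calibration()),
                   enhance_params(spatial_detrend_window = 51,
                                  temporal_lowpass_window = 5))
  # crest = per-frame argmax, away from the detrend edge effects
  frames <- 10:(nt - 10)
  crest <- sapply(frames, function(t) which.max(e$values[, t + 1]) - 1)
  fit <- stats::lm(crest ~ frames)
  expect_equal(unname(fit$coefficients[2]), v, tolerance = 0.05)

  expect_error(enhance_map(st_map(matrix(1, 3, 3), "mean_intensity", calibration())),
               class = "myowave_size_error")
})

test_that("masked cells never acquire fabricated values through the pipeline", {
  m <- matrix(rnorm(40 * 30, 100, 5), 40, 30)
  m[1:4, ] <- NA
  e <- enhance_map(st_map(m, "mean_intensity", calibration()),
                   enhance_params(spatial_detrend_window = 11,
                                  temporal_lowpass_window = 3))
  expect_true(all(is.na(e$values[1:4, ])))
  expect_true(all(!is.na(e$values[10:40, ])))
})

test_that("enhanced intensity ridges track the true wave loci", {
  sim <- quick_sim(width = 500, height = 80, duration_s = 30, r0 = 20,
                   wave_speed_um_s = 60, noise_sd = 2, seed = 3)
  res <- run_pipeline(sim$stack)
  e <- res$enhanced_intensity
  # the enhancement marks a wave as a band of change flanking the crest, so
  # the band's centre of mass (not a single argmax) should sit on the crest
  margin <- 80
  half <- ceiling(sim$truth$w_px * 0.7)
  hits <- 0; total <- 0
  for (t in seq_len(ncol(e$values)) - 1) {
    crests <- crest_columns_at(sim$truth, t)
    crests <- crests[crests > margin & crests < nrow(e$values) - margin]
    for (cr in crests) {
      win <- (round(cr) - half):(round(cr) + half)
      v <- pmax(e$values[win + 1, t + 1], 0)
      if (all(is.na(v)) || sum(v, na.rm = TRUE) == 0) next
      centroid <- sum(win * v, na.rm = TRUE) / sum(v, na.rm = TRUE)
      total <- total + 1
      if (abs(centroid - cr) <= 3) hits <- hits + 1
    }
  }
  expect_gte(total, 50)
  expect_gte(hits / total, 0.9)
})

test_that("st_map tidiers and plots expose calibrated axes", {
  m <- st_map(matrix(1:6, 3, 2), "area_px", calibration())
  td <- tidy(m)
  expect_equal(nrow(td), 6)
  expect_equal(td$position_mm[2], 1 / 110.85)
  expect_equal(td$time_s[4], 1 / 5)
  g <- glance(m)
  expect_equal(g$n_columns, 3)
  expect_s3_class(autoplot(m), "ggplot")
})
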