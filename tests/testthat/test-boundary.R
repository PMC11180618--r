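test_that("stack smoothing preserves constants and total mass", {
  const <- frame_stack(array(100, c(20, 30, 5)), 0.2)
  sm <- smooth_stack(const)
  expect_equal(sm$frames, const$frames)

  # single bright impulse keeps its mass (kernels are normalised; the
  # impulse sits away from edges so no replicate-padding leakage)
  imp <- array(0, c(21, 21, 7))
  imp[11, 11, 4] <- 255
  sm2 <- smooth_stack(frame_stack(imp, 0.2))
  expect_equal(sum(sm2$frames), 255, tolerance = 1e-10)

  # size-1 kernels are the identity
  p1 <- boundary_params(t_kernel = 1, s_kernel = 1)
  fs <- quick_sim(width = 128, height = 48, duration_s = 2, r0 = 12)$stack
  expect_equal(smooth_stack(smooth_stack(fs, p1), p1)$frames, fs$frames)

  expect_error(smooth_stack(frame_stack(array(1, c(5, 5, 2)), 0.2),
                            boundary_params(t_kernel = 5)),
               class = "myowave_insufficient_frames_error")
})

test_that("edge index weights the vertical Sobel response", {
  p <- boundary_params()
  expect_equal(edge_index(matrix(7, 20, 20), p), matrix(0, 20, 20))

  row_ramp <- matrix(rep(seq_len(20), times = 25), 20, 25)   # varies along rows only
  s_h <- edge_index(row_ramp, boundary_params(vertical_weight = 0))
  expect_equal(edge_index(row_ramp, p), s_h)                  # S_v = 0 here

  col_ramp <- t(matrix(rep(seq_len(25), times = 20), 25, 20)) # varies along columns only
  unweighted <- edge_index(col_ramp, boundary_params(vertical_weight = 1))
  expect_equal(edge_index(col_ramp, p), 2 * unweighted)
  expect_gt(max(abs(unweighted)), 0)

  expect_error(edge_index(matrix(0, 3, 3), p), class = "myowave_size_error")
})

test_that("cumulative-sum crossings locate a bright band", {
  fr <- band_frame(height = 100, width = 60, band_rows = 41:61)
  b <- detect_boundaries(edge_index(fr))
  expect_true(all(b$valid))
  expect_true(all(abs(b$upper - 40) <= 2))
  expect_true(all(abs(b$lower - 60) <= 2))

  empty <- detect_boundaries(matrix(0, 50, 20))
  expect_false(any(empty$valid))
})

test_that("detection is equivariant to vertical flips", {
  fr <- band_frame(height = 100, width = 40, band_rows = 31:51)
  b <- detect_boundaries(edge_index(fr))
  bf <- detect_boundaries(edge_index(fr[100:1, ]))
  expect_equal(bf$valid, b$valid)
  expect_equal(bf$upper, 99 - b$lower)
  expect_equal(bf$lower, 99 - b$upper)
})

test_that("normalised profile makes detection intensity-scale invariant", {
  fr <- band_frame(height = 100, width = 40, band_rows = 36:66, level = 120)
  b1 <- detect_boundaries(edge_index(fr))
  b2 <- detect_boundaries(edge_index(fr * 1.9))
  expect_true(all(abs(b1$upper - b2$upper) <= 0.5, na.rm = TRUE))
  expect_true(all(abs(b1$lower - b2$lower) <= 0.5, na.rm = TRUE))
})

test_that("spline smoothing reproduces smooth boundaries and rejects spikes", {
  nc <- 101
  linear <- tibble::tibble(
    column = 0:(nc - 1),
    upper = 10 + 0.2 * (0:(nc - 1)),
    lower = 60 + 0.1 * (0:(nc - 1)),
    valid = TRUE
  )
  sm <- smooth_boundaries(linear, height = 100)
  expect_equal(sm$upper, linear$upper, tolerance = 1e-8)
  expect_equal(sm$lower, linear$lower, tolerance = 1e-8)

  spiked <- linear
  spiked$upper[16] <- spiked$upper[16] + 30   # column 15: between knots 10 and 20
  sm2 <- smooth_boundaries(spiked, height = 100)
  expect_lt(abs(sm2$upper[16] - linear$upper[16]), 3)

  const <- tibble::tibble(column = 0:50, upper = 20, lower = 40, valid = TRUE)
  smc <- smooth_boundaries(const, height = 100)
  expect_equal(smc$upper, rep(20, 51))

  few <- tibble::tibble(column = 0:50, upper = 20, lower = 40,
                        valid = c(rep(TRUE, 3), rep(FALSE, 48)))
  expect_false(any(smooth_boundaries(few, height = 100)$valid))
})

test_that("boundary crossings are clamped to preserve non-negative area", {
  nc <- 61
  raw <- tibble::tibble(
    column = 0:(nc - 1),
    upper = 30 + 8 * sin((0:(nc - 1)) / 3),
    lower = 30 - 8 * sin((0:(nc - 1)) / 3),
    valid = TRUE
  )
  sm <- smooth_boundaries(raw, height = 100)
  expect_true(all(sm$upper[sm$valid] < sm$lower[sm$valid]))
})

test_that("noise-free simulated tubes are traced within 2 px on average", {
  sim <- quick_sim(width = 400, height = 80, duration_s = 10, r0 = 20)
  b <- trace_boundaries(sim$stack)
  expect_lt(boundary_mae(b, sim$truth), 2)
})

test_that("an isolated blob between knots is rejected by the spline", {
  # bright blob well below the band, narrow enough to fall between two
  # spline knots: the raw lower boundary jumps to the blob there, but the
  # interpolated boundary is rebuilt from the unperturbed knot columns
  fr <- band_frame(height = 120, width = 101, band_rows = 41:61)
  blob_cols <- 14:18                     # 0-based 13..17, strictly between knots 10 and 20
  fr[95:99, blob_cols] <- 220
  raw_clean <- detect_boundaries(edge_index(band_frame(height = 120, width = 101,
                                                       band_rows = 41:61)))
  raw_blob <- detect_boundaries(edge_index(fr))
  expect_gt(max(raw_blob$lower - raw_clean$lower, na.rm = TRUE), 20)
  sm_clean <- smooth_boundaries(raw_clean, height = 120)
  sm_blob <- smooth_boundaries(raw_blob, height = 120)
  expect_lt(max(abs(sm_blob$lower - sm_clean$lower), na.rm = TRUE), 3)
})

test_that("stain-like blobs outside the tube leave the trace usable", {
  stained <- quick_sim(width = 600, height = 120, duration_s = 8, r0 = 20,
                       artifact_count = 3, seed = 7)
  bs <- trace_boundaries(stained$stack)
  expect_lt(boundary_mae(bs, stained$truth), 4)
})
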