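test_that("degenerate synthesis specs are rejected", {
  expect_error(synthesis_spec(target_rms_contrast = 0), "positive")
  expect_error(synthesis_spec(mean_luminance = -1), "positive")
  expect_error(synthesis_spec(width_px = 721L), "even")
  expect_error(panorama(matrix(-1, 4, 8), 45, c(-90, 90)), "non-negative")
  expect_error(panorama(matrix(1, 4, 10), 45, c(-90, 90)), "360")
})

test_that("natural synthesis is deterministic and leaves the RNG alone", {
  spec <- synthesis_spec(width_px = 720L, height_px = 140L, seed = 11)
  set.seed(99)
  p1 <- generate_natural_panorama(spec)
  draw1 <- rnorm(1)
  p2 <- generate_natural_panorama(spec)
  expect_identical(p1$luminance, p2$luminance)
  set.seed(99)
  expect_identical(rnorm(1), draw1)  # generator restored the RNG state
})

test_that("natural panoramas meet their statistical contracts", {
  for (sd_ in 1:20) {
    p <- generate_natural_panorama(
      synthesis_spec(width_px = 720L, height_px = 140L, seed = sd_))
    L <- p$luminance
    expect_true(all(L >= 0))
    expect_equal(mean(L), 100, tolerance = 1e-6)
    expect_equal(rms_contrast(p), 0.4, tolerance = 0.02)
    top <- seq_len(nrow(L) %/% 2)
    cu <- sd(L[top, ]) / mean(L[top, ])
    cl <- sd(L[-top, ]) / mean(L[-top, ])
    expect_equal(cl / cu, 3, tolerance = 0.1)
  }
})

test_that("amplitude spectrum of the default synthesis falls as 1/f", {
  p <- generate_natural_panorama(synthesis_spec(seed = 7))
  expect_equal(spectrum_slope(p), -1, tolerance = 0.15)
})

test_that("the azimuthal seam is statistically invisible", {
  p <- generate_natural_panorama(
    synthesis_spec(width_px = 720L, height_px = 140L, seed = 5))
  L <- p$luminance
  W <- ncol(L)
  seam <- mean((L[, 1] - L[, W])^2)        # wraparound neighbour pair
  interior <- mean((L[, -1] - L[, -W])^2)  # all interior neighbour pairs
  expect_lt(abs(seam / interior - 1), 0.5)
})

test_that("sine panoramas follow the closed-form luminance profile", {
  expect_error(generate_sine_panorama(33), "integer")
  p0 <- generate_sine_panorama(30, contrast = 0, width_px = 144L,
                               height_px = 16L)
  expect_true(all(p0$luminance == 100))
  p <- generate_sine_panorama(30, contrast = 0.5, mean_luminance = 100,
                              width_px = 1440L, height_px = 16L)
  expect_equal(min(p$luminance), 50, tolerance = 1e-4)
  expect_equal(max(p$luminance), 150, tolerance = 1e-4)
  # Eq for RMS contrast of a sinusoid: c / sqrt(2)
  expect_equal(rms_contrast(p), 0.5 / sqrt(2), tolerance = 1e-12)
})

test_that("step panoramas have exactly one rising and one falling edge", {
  p <- generate_step_panorama(180, low = 10, high = 100,
                              width_px = 720L, height_px = 16L)
  row <- p$luminance[1, ]
  d <- diff(c(row, row[1]))   # wrap the seam
  expect_identical(sum(d != 0), 2L)
  expect_identical(sum(d > 0), 1L)
  flat <- generate_step_panorama(180, low = 7, high = 7, width_px = 720L,
                                 height_px = 16L)
  expect_true(all(flat$luminance == 7))
})

test_that("binary round trip is bit-exact, TIFF round trip is close", {
  p <- coarse_panorama(seed = 9)
  path <- tempfile(fileext = ".bin")
  write_panorama(p, path)
  q <- read_panorama(path)
  expect_identical(q$luminance, p$luminance)
  expect_identical(q$deg_per_pixel, p$deg_per_pixel)
  expect_identical(q$elevation_range, p$elevation_range)
  expect_error(read_panorama(tempfile()), "not found")
  if (requireNamespace("tiff", quietly = TRUE)) {
    tpath <- tempfile(fileext = ".tif")
    write_panorama(p, tpath)
    qt <- read_panorama(tpath)
    expect_equal(qt$luminance, p$luminance, tolerance = 1e-6)
  }
})
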