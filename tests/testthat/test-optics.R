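test_that("Gaussian prefilter passes DC, conserves flux, has the right width", {
  const <- panorama(matrix(42, 140, 720), 0.5, c(-35, 35))
  expect_equal(gaussian_prefilter(const, 4)$luminance,
               const$luminance, tolerance = 1e-12)
  # resolution guard
  expect_error(gaussian_prefilter(const, 1.64), "coarse")

  # impulse response: discrete Gaussian, unchanged sum, FWHM = delta_rho
  L <- matrix(0, 280, 1440)          # 0.25 deg/px
  L[140, 720] <- 1
  imp <- gaussian_prefilter(panorama(L, 0.25, c(-35, 35)), 1.64)$luminance
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  prof <- imp[140, ] / max(imp)
  half_px <- 0.82 / 0.25             # half the acceptance angle, in px
  i <- 720 + floor(half_px); f <- half_px - floor(half_px)
  v <- prof[i] * (1 - f) + prof[i + 1] * f
  expect_equal(v, 0.5, tolerance = 0.02)

  # sinusoid attenuated by the Gaussian transfer function exp(-2 pi^2 s^2 / l^2)
  p <- generate_sine_panorama(30, contrast = 0.5, width_px = 1440L,
                              height_px = 64L, deg_per_pixel = 0.25)
  pf <- gaussian_prefilter(p, 1.64)
  sigma <- 1.64 / (2 * sqrt(2 * log(2)))
  att <- exp(-2 * pi^2 * sigma^2 / 30^2)
  amp_ratio <- (max(pf$luminance) - 100) / (max(p$luminance) - 100)
  expect_equal(amp_ratio, att, tolerance = 1e-3)
})

test_that("receptor sampling interpolates bilinearly and wraps at 360", {
  p <- coarse_panorama(seed = 2)
  # rows chosen on exact pixel centres of the 0.5 deg/px raster
  g <- receptor_grid(phi = 5,
                     elevation_of_row = c(20.25, 10.25, 0.25, -10.25))
  s0 <- sample_receptors(p, g, 0)
  # receptors sit on exact pixel centres of the 0.5 deg/px raster
  cols <- round(g$azimuth_of_col / p$deg_per_pixel) + 1L
  rows <- round((p$elevation_range[2] - g$elevation_of_row) /
                  p$deg_per_pixel + 0.5)
  expect_equal(s0, p$luminance[rows, cols], tolerance = 1e-12)
  expect_equal(sample_receptors(p, g, 360), s0, tolerance = 1e-12)
  expect_equal(sample_receptors(p, g, -720), s0, tolerance = 1e-12)
  # half-pixel offset averages horizontally adjacent pixels
  s_half <- sample_receptors(p, g, -p$deg_per_pixel / 2)
  right <- cols + 1L
  expect_equal(s_half, (p$luminance[rows, cols] +
                          p$luminance[rows, right]) / 2,
               tolerance = 1e-12)
  bad <- receptor_grid(phi = 5, elevation_of_row = c(50, 40))
  expect_error(sample_receptors(p, bad, 0), "elevation")
})

test_that("Naka-Rushton is the bounded midpoint-at-I0 transduction", {
  expect_equal(naka_rushton(7, 7), 0.5)
  expect_equal(naka_rushton(0, 5), 0)
  expect_equal(naka_rushton(10, 1, a = 0.7), 10^0.7 / (10^0.7 + 1),
               tolerance = 1e-12)
  expect_error(naka_rushton(-1, 1), "non-negative")
  x <- seq(0, 50, by = 0.5)
  u <- naka_rushton(x, 5)
  expect_true(all(diff(u) > 0) && all(u >= 0 & u < 1))
})

test_that("I0 is the geometric mean of the scene luminance", {
  expect_equal(estimate_I0(matrix(3, 4, 4)), 3)
  expect_equal(estimate_I0(matrix(c(1, 100), 2, 10)), 10, tolerance = 1e-9)
  L <- coarse_panorama(seed = 4)
  expect_equal(estimate_I0(5 * L$luminance), 5 * estimate_I0(L),
               tolerance = 1e-9)
  expect_error(estimate_I0(matrix(0, 3, 3)), "all-zero")
})

test_that("recursive filters match closed forms and complement exactly", {
  # unit step into LP(tau = 8, dt = 1): y_k = 1 - exp(-k/8)
  y <- lp_filter(rep(1, 8), 8, 1, y0 = 0)
  expect_equal(y[8], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(y, 1 - exp(-(1:8) / 8), tolerance = 1e-12)
  # DC gains
  expect_equal(lp_filter(rep(3, 5000), 40, 1, y0 = 0)[5000], 3,
               tolerance = 1e-9)
  expect_lt(abs(hp_filter(rep(3, 5000), 400, 1, y0 = 0)[5000]), 1e-4)
  # LP + complementary HP reconstruct the input at every step
  set.seed(1)
  x <- cumsum(rnorm(400))
  expect_equal(lp_filter(x, 25, 1) + hp_filter(x, 25, 1), x,
               tolerance = 1e-12)
  # step interface agrees with the trace interface
  st <- filter_state(8)
  ys <- numeric(8)
  for (t in 1:8) {
    r <- lowpass_step(st, if (t == 1) 0 else 1, 1)  # y0 = first sample = 0
    ys[t] <- r$y; st <- r$state
  }
  expect_equal(ys[-1], lp_filter(rep(1, 8), 8, 1, y0 = 0)[-8],
               tolerance = 1e-12)
})

test_that("the front end is luminance-compressive across scenes", {
  p <- coarse_panorama(seed = 6)
  g <- coarse_grid(rows = 7)
  opt <- coarse_optics()
  I0 <- estimate_I0(p)   # fixed working point, not re-adapted to the scale
  bp_sd <- function(pan) {
    pf <- gaussian_prefilter(pan, opt$delta_rho)
    tr <- sapply(0:399, function(t)
      sample_receptors(pf, g, t * 60 * 1e-3)[1, 1])
    u <- naka_rushton(tr, I0, opt$a_nr)
    sd(hp_filter(lp_filter(u, opt$tau_L, 1), opt$tau_H, 1))
  }
  p100 <- panorama(100 * p$luminance, p$deg_per_pixel, p$elevation_range)
  expect_lt(bp_sd(p100) / bp_sd(p), 100)
})
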