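test_that("basic correlator prefers motion toward increasing azimuth", {
  n <- 4000; dt <- 1
  om <- 2 * pi / 500                       # 2 Hz temporal frequency
  lag <- 2 * pi * 1.25 / 30                # spatial phase lag of 1.25 deg
  t <- seq_len(n)
  # preferred drift: the right receptor sees what the left saw earlier
  pref <- basic_emd(sin(om * t), sin(om * t - lag), 40, dt)
  null <- basic_emd(sin(om * t - lag), sin(om * t), 40, dt)
  keep <- 1001:n
  expect_gt(mean(pref$P_plus[keep]), mean(pref$P_minus[keep]))
  # mirror symmetry swaps the two half-detector means exactly
  expect_equal(mean(pref$P_plus[keep]), mean(null$P_minus[keep]),
               tolerance = 1e-12)
  expect_equal(mean(pref$P_minus[keep]), mean(null$P_plus[keep]),
               tolerance = 1e-12)
  # rectification contract and zero-input behaviour
  expect_true(all(pref$P_plus >= 0) && all(pref$P_minus >= 0))
  z <- basic_emd(numeric(10), numeric(10))
  expect_true(all(z$P_plus == 0) && all(z$P_minus == 0))
})

test_that("adaptive time constant relaxes and equilibrates as designed", {
  pars <- emd_params("adaptive")
  th <- 250
  for (i in 1:20000) th <- update_tau_h(th, 0, g = 1, dt = 1, pars)
  expect_equal(th, pars$max_tauh, tolerance = 1e-6)
  th <- 250
  for (i in 1:100) th <- update_tau_h(th, 1e6, g = 1, dt = 1, pars)
  expect_lt(th, 1e-3)   # overwhelming drive pins tau_h at its floor
  # constant drive: fixed point (K max + gS min) / (K + gS)
  g <- 2; S <- 0.05
  th <- 250
  for (i in 1:60000) th <- update_tau_h(th, S, g, dt = 1, pars)
  expect_equal(th, (pars$K * pars$max_tauh + g * S * pars$min_tauh) /
                 (pars$K + g * S), tolerance = 1e-6)
  expect_true(all(sapply(c(0, 1, 100), function(S)
    update_tau_h(500, S, 1, 1, pars) <= pars$max_tauh)))
})

test_that("saturation gain calibration is homogeneous and maps q75 to tanh(1)", {
  expect_equal(estimate_saturation_gain(matrix(2, 10, 3)), 0.5)
  set.seed(2)
  x <- matrix(rnorm(500), 100)
  expect_equal(estimate_saturation_gain(3 * x),
               estimate_saturation_gain(x) / 3, tolerance = 1e-12)
  a <- estimate_saturation_gain(x)
  q75 <- mean(apply(abs(x), 2, quantile, 0.75))
  expect_equal(saturate_input(q75, a), tanh(1), tolerance = 1e-12)
  expect_identical(saturate_input(0, a), 0)
  expect_equal(saturate_input(-x, a), -saturate_input(x, a))
  expect_error(estimate_saturation_gain(numeric(0)), "empty")
  expect_error(estimate_saturation_gain(matrix(0, 5, 2)), "degenerate")
})

test_that("input-line gain control normalizes the signal scale", {
  # constant positive input: mad -> c, output -> c / (c + eps) ~ 1
  y <- input_gain_control(rep(2, 5000), tau_A = 200, dt = 1, eps = 1e-9)
  expect_equal(y[5000], 1, tolerance = 1e-6)
  expect_true(all(input_gain_control(numeric(50)) == 0))
  # settled periodic outputs are amplitude-invariant to first order
  t <- seq_len(6000)
  x <- sin(2 * pi * t / 200)
  y1 <- input_gain_control(x, 200, 1, 1e-9)
  y2 <- input_gain_control(10 * x, 200, 1, 1e-9)
  keep <- 4001:6000
  expect_equal(sd(y2[keep]) / sd(y1[keep]), 1, tolerance = 1e-3)
})

test_that("EMD field geometry: n receptors give n-1 sites, rings close", {
  set.seed(4)
  tr2 <- matrix(rnorm(100 * 2), 100)
  expect_identical(dim(build_emd_field(tr2)$P_plus)[3], 1L)
  tr4 <- matrix(rnorm(100 * 4), 100)
  expect_identical(dim(build_emd_field(tr4)$P_plus)[3], 3L)
  tr24 <- array(rnorm(100 * 2 * 24), c(100, 2, 24))
  ring <- build_emd_field(tr24, periodic = TRUE)
  expect_identical(dim(ring$P_plus)[3], 24L)
  expect_true(all(ring$P_plus >= 0) && all(ring$P_minus >= 0))
  # the wraparound site correlates the last column with the first
  open_ <- build_emd_field(tr24)
  expect_equal(ring$P_plus[, , 1:23], open_$P_plus, tolerance = 1e-12)
  expect_error(build_emd_field(matrix(rnorm(10), 10, 1)), "2 receptor")
})

test_that("contrast-response exponent is 2 for the basic correlator and
          below 2 with saturating input lines", {
  g <- coarse_grid(rows = 7)
  stim <- stimulus_spec(velocity = 60, duration = 4, discard = 2)
  rf <- rect_rf(1, g$n_az, g)
  mean_z <- function(variant, contrast) {
    p <- generate_sine_panorama(30, contrast, 100, width_px = 720L,
                                height_px = 140L)
    mean(run_simulation(p, variant, list(rf), stim, grid = g,
                        optics = coarse_optics())[[1]]$Z)
  }
  r_basic <- mean_z("basic", 0.04) / mean_z("basic", 0.02)
  expect_equal(r_basic, 4, tolerance = 0.05)
  for (v in c("saturation", "input_gain")) {
    expo <- log2(mean_z(v, 0.04) / mean_z(v, 0.02))
    expect_lt(expo, 1.9)
  }
})
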