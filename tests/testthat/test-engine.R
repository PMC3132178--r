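# The compiled streaming engine is validated against the pure-R pipeline
# assembled from the exported per-operation functions, then its contracts
# (determinism, trace bookkeeping, stationarity, periodicity, direction
# antisymmetry) are checked on their own.

test_that("compiled engine reproduces the pure-R reference pipeline", {
  p <- coarse_panorama(seed = 3)
  g <- coarse_grid(rows = 6:8)
  stim <- stimulus_spec(velocity = 60, duration = 1.5, discard = 0.25)
  rfs <- list(rect_rf(2, 6, g), rect_rf(g$n_elev, g$n_az, g))
  for (v in c("basic", "saturation", "input_gain")) {
    emd <- emd_params(v, a_sat = 5, eps_gain = 1e-8)
    a <- run_simulation(p, v, rfs, stim, grid = g,
                        optics = coarse_optics(), emd = emd)
    b <- flymotion:::r_reference_response(p, v, rfs, stim, grid = g,
                                          optics = coarse_optics(),
                                          emd = emd)
    for (k in 1:2)
      expect_equal(a[[k]]$Z, b[[k]]$Z, tolerance = 1e-12)
  }
  # adaptive variant on a smaller case (the R path iterates per channel)
  g2 <- receptor_grid(phi = 15,
                      elevation_of_row = coarse_grid()$elevation_of_row[7:8])
  stim2 <- stimulus_spec(velocity = 60, duration = 0.8, discard = 0.2)
  rfs2 <- list(rect_rf(2, 5, g2), rect_rf(2, g2$n_az, g2))
  emd2 <- emd_params("adaptive", g_adapt = 0.7)
  a <- run_simulation(p, "adaptive", rfs2, stim2, grid = g2,
                      optics = coarse_optics(), emd = emd2)
  b <- flymotion:::r_reference_response(p, "adaptive", rfs2, stim2,
                                        grid = g2,
                                        optics = coarse_optics(),
                                        emd = emd2)
  for (k in 1:2)
    expect_equal(a[[k]]$Z, b[[k]]$Z, tolerance = 1e-12)
})

test_that("identical inputs give bit-identical traces", {
  p <- coarse_panorama(seed = 12)
  g <- coarse_grid(rows = 7)
  stim <- stimulus_spec(velocity = 60, duration = 1, discard = 0.2)
  rfs <- list(rect_rf(1, g$n_az, g))
  r1 <- run_simulation(p, "input_gain", rfs, stim, grid = g,
                       optics = coarse_optics())
  r2 <- run_simulation(p, "input_gain", rfs, stim, grid = g,
                       optics = coarse_optics())
  expect_identical(r1[[1]]$Z, r2[[1]]$Z)
})

test_that("trace bookkeeping: 12 s at 1 kHz minus 6 s leaves 6000 samples", {
  p <- generate_natural_panorama(synthesis_spec(seed = 2))
  g <- receptor_grid(n_elev = 1)
  res <- run_simulation(p, "basic", list(rect_rf(1, 2, g)),
                        stimulus_spec(), grid = g)
  expect_identical(length(res[[1]]$Z), 6000L)
  expect_identical(res[[1]]$t_ms[1], 6000)
  expect_true(all(abs(res[[1]]$Z) < 1))
})

test_that("a stationary panorama evokes no response", {
  p <- coarse_panorama(seed = 5)
  g <- coarse_grid(rows = 6:8)
  res <- run_simulation(p, "basic", list(rect_rf(3, g$n_az, g)),
                        stimulus_spec(velocity = 0, duration = 3,
                                      discard = 2.5),
                        grid = g, optics = coarse_optics())
  expect_lt(max(abs(res[[1]]$Z)), 1e-9)
})

test_that("the retained trace of a periodic stimulus is itself periodic", {
  p <- coarse_panorama(seed = 8)
  g <- coarse_grid(rows = 7)
  stim <- stimulus_spec(velocity = 60, duration = 18, discard = 6)
  res <- run_simulation(p, "basic", list(rect_rf(1, g$n_az, g)), stim,
                        grid = g, optics = coarse_optics())
  z <- res[[1]]$Z
  rot2 <- z[1:6000]; rot3 <- z[6001:12000]
  expect_equal(rot2, rot3, tolerance = 1e-4)
})

test_that("mirroring the scene and reversing motion flips the response", {
  p <- coarse_panorama(seed = 10)
  g <- coarse_grid(rows = 6:8)
  stim_f <- stimulus_spec(velocity = 60, duration = 2, discard = 0.5)
  stim_r <- stimulus_spec(velocity = -60, duration = 2, discard = 0.5)
  rf <- rect_rf(3, g$n_az, g)
  zf <- run_simulation(p, "basic", list(rf), stim_f, grid = g,
                       optics = coarse_optics())[[1]]$Z
  zr <- run_simulation(mirror_panorama(p), "basic", list(rf), stim_r,
                       grid = g, optics = coarse_optics())[[1]]$Z
  expect_equal(zr, -zf, tolerance = 1e-10)
})

test_that("a drifting grating drives the full ring at constant amplitude", {
  # wavelength incommensurate with the receptor spacing (28.8 receptors
  # per cycle), so per-site discretization residuals cancel around the ring
  p <- generate_sine_panorama(36, contrast = 0.5, width_px = 2880L,
                              height_px = 560L)
  g <- receptor_grid(n_elev = 1)
  res <- run_simulation(p, "basic", list(rect_rf(1, g$n_az, g)),
                        stimulus_spec(velocity = 60, duration = 8,
                                      discard = 6),
                        grid = g)
  z <- res[[1]]$Z
  expect_gt(mean(z), 0)
  expect_lt(sd(z) / mean(z), 1e-3)
})

test_that("simulate() drives a model object end to end", {
  g <- coarse_grid(rows = 6:8)
  m <- lptc_model("basic", rf = rect_rf(3, g$n_az, g), grid = g,
                  optics = coarse_optics())
  expect_output(print(m), "basic")
  r <- simulate(m, panorama = coarse_panorama(seed = 1),
                stimulus = stimulus_spec(velocity = 60, duration = 1.5,
                                         discard = 0.5))
  expect_s3_class(r, "lptc_response")
  expect_identical(length(r$Z), 1000L)
  expect_output(print(r), "retained")
})
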