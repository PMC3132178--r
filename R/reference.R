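# Pure-R reference pipeline: panorama -> receptor traces -> band-pass ->
# EMD field -> gain-control integration, built from the exported
# per-operation functions. Slow (R loops) but transparent; used in the test
# suite as the independent oracle for the compiled engine. Calibrated
# constants (a_sat, eps_gain, g_adapt) must be supplied explicitly so both
# paths see identical parameters.
r_reference_response <- function(p, variant, rf_list,
                                 stim = stimulus_spec(),
                                 grid = receptor_grid(),
                                 optics = optics_params(),
                                 emd = emd_params(),
                                 gain = gain_control_params(),
                                 prefiltered = FALSE) {
  emd$variant <- variant
  pf <- if (prefiltered) p else gaussian_prefilter(p, optics$delta_rho)
  prof <- receptor_row_profiles(pf, grid)
  I0 <- if (is.null(optics$I0)) estimate_I0(p) else optics$I0
  Tn <- stim$n_steps
  nr <- grid$n_elev; na_ <- grid$n_az

  # receptor luminance traces under image motion
  I <- array(0, c(Tn, nr, na_))
  for (t in seq_len(Tn)) {
    shift <- stim$velocity * (t - 1) * stim$dt / 1000
    idx <- azimuth_sample_index(grid$azimuth_of_col - shift,
                                pf$deg_per_pixel, ncol(pf$luminance))
    I[t, , ] <- prof[, idx$i0, drop = FALSE] *
      rep(1 - idx$f, each = nr) +
      prof[, idx$i1, drop = FALSE] * rep(idx$f, each = nr)
  }

  u <- naka_rushton(I, I0, optics$a_nr)
  bp <- u
  for (i in seq_len(nr)) for (j in seq_len(na_)) {
    y1 <- lp_filter(u[, i, j], optics$tau_L, stim$dt)
    bp[, i, j] <- hp_filter(y1, optics$tau_H, stim$dt)
  }

  fld <- build_emd_field(bp, emd, stim$dt, periodic = TRUE)
  keep <- seq.int(stim$n_discard + 1L, Tn)
  lapply(rf_list, function(rf) {
    z <- numeric(Tn)
    for (t in seq_len(Tn))
      z[t] <- gain_control_integrate(fld$P_plus[t, , ],
                                     fld$P_minus[t, , ],
                                     w = rf$w, gc = gain)
    structure(list(Z = z[keep], t_ms = (keep - 1L) * stim$dt,
                   dt = stim$dt, variant = variant, rf = rf,
                   stimulus = stim, I0 = I0),
              class = "lptc_response")
  })
}
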