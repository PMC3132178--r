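#' Pattern-noise reduction study over synthetic panoramas
#'
#' Runs the standard protocol quantifying how much spatial pooling reduces
#' pattern-dependent response modulations: for each seeded synthetic
#' panorama and each detector variant, simulate constant-velocity
#' preferred-direction rotation (12 s at 60 deg/s, 1 kHz, first rotation
#' discarded), compute the modulation SD of a small reference array (two
#' receptors, one EMD, centred at the horizon) and of a large array, and
#' report the percentage reduction.
#'
#' The large array is either a one-row horizontal array of `n_large`
#' receptors (`geometry = "1d"`) or an `m_rows x m_rows`-receptor square
#' (`geometry = "square"`), both centred on the horizon and on the vertical
#' axis of the image. The front end simulates one receptor row for the 1-D
#' geometry (its full-field reference is the closed one-row ring, which for
#' the SD comparison is indistinguishable from the whole-image reference)
#' and the whole grid for the square, whose reference is the full-image
#' ring.
#'
#' @param seeds integer vector of panorama seeds.
#' @param variants detector variants to run.
#' @param geometry `"1d"` or `"square"`.
#' @param n_large horizontal receptor count of the large 1-D array.
#' @param m_rows side length (in receptors) of the square array.
#' @param spec a [synthesis_spec()]; its `seed` is replaced per image.
#' @param stim a [stimulus_spec()].
#' @param grid the full [receptor_grid()] rows are drawn from.
#' @param verbose print one line per (image, variant).
#' @return data frame with columns `image`, `variant`, `s_small`,
#'   `s_large`, `reduction` (percent).
#' @export
pattern_noise_study <- function(seeds = 1:5,
                                variants = c("basic", "adaptive",
                                             "saturation", "input_gain"),
                                geometry = c("1d", "square"),
                                n_large = 256, m_rows = 16,
                                spec = synthesis_spec(),
                                stim = stimulus_spec(),
                                grid = receptor_grid(),
                                verbose = FALSE) {
  geometry <- match.arg(geometry)
  sub <- if (geometry == "1d")
    receptor_grid(phi = grid$phi,
                  elevation_of_row = grid$elevation_of_row[
                    centred_indices(grid$n_elev, 1L)])
  else grid
  horizon_row <- centred_indices(sub$n_elev, 1L)

  rf_small <- rect_rf(1, 2, sub)
  rf_small$w[] <- 0
  rec <- centred_receptor_cols(2, sub, 180)
  rf_small$w[horizon_row, rec[1]] <- 1
  rf_large <- if (geometry == "1d") rect_rf(1, n_large, sub)
              else rect_rf(m_rows, m_rows, sub)
  rf_ref <- rect_rf(sub$n_elev, sub$n_az, sub)

  out <- vector("list", length(seeds) * length(variants))
  k <- 0L
  for (sd_ in seeds) {
    spec$seed <- as.integer(sd_)
    p <- generate_natural_panorama(spec)
    pf <- gaussian_prefilter(p, optics_params()$delta_rho)
    for (v in variants) {
      res <- run_simulation(pf, v, list(rf_small, rf_large, rf_ref),
                            stim, grid = sub, prefiltered = TRUE)
      N_ref <- normalize_response(res[[3]])
      s_small <- modulation_sd(normalize_response(res[[1]]), N_ref)
      s_large <- modulation_sd(normalize_response(res[[2]]), N_ref)
      k <- k + 1L
      out[[k]] <- data.frame(image = sd_, variant = v,
                             s_small = s_small, s_large = s_large,
                             reduction = reduction_percentage(s_small,
                                                             s_large))
      if (verbose)
        cat(sprintf("seed %d %-11s s2=%.4f s_large=%.5f reduction=%.1f%%\n",
                    sd_, v, s_small, s_large, out[[k]]$reduction))
    }
  }
  do.call(rbind, out)
}
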