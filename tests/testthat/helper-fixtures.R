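# Shared fixtures, built in code once per test run.

# coarse configuration: 5-degree receptor spacing (72-receptor ring),
# 0.5 deg/px rasters, wide acceptance angle to keep the prefilter happy at
# that resolution -- cheap enough for pure-R reference runs
coarse_grid <- function(rows = NULL) {
  g <- receptor_grid(phi = 5)
  if (is.null(rows)) g
  else receptor_grid(phi = 5, elevation_of_row = g$elevation_of_row[rows])
}
coarse_optics <- function() optics_params(delta_rho = 4)

coarse_panorama <- function(seed = 3, contrast = 0.4)
  generate_natural_panorama(synthesis_spec(width_px = 720L,
                                           height_px = 140L, seed = seed,
                                           target_rms_contrast = contrast))

# slope of the radially averaged log-log amplitude spectrum (DC excluded);
# independent periodogram-based check of the 1/f^beta synthesis
spectrum_slope <- function(p, f_lo = 0.01, f_hi = 0.2) {
  L <- p$luminance
  A <- Mod(stats::fft(L - mean(L)))
  fy <- flymotion:::fft_freq(nrow(L))
  fx <- flymotion:::fft_freq(ncol(L))
  f <- sqrt(outer(fy^2, fx^2, `+`))
  sel <- f > f_lo & f < f_hi
  bins <- cut(log10(f[sel]), 24)
  la <- tapply(log10(A[sel]), bins, mean)
  lf <- tapply(log10(f[sel]), bins, mean)
  ok <- is.finite(la) & is.finite(lf)
  unname(stats::coef(stats::lm(la[ok] ~ lf[ok]))[2])
}

# mirror a panorama in azimuth (reflection about the azimuth-0 pixel line)
mirror_panorama <- function(p) {
  L <- p$luminance
  W <- ncol(L)
  M <- L[, c(1L, W:2L), drop = FALSE]
  panorama(M, p$deg_per_pixel, p$elevation_range, p$periodic_azimuth)
}
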