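#' Panoramic luminance image
#'
#' Container for a horizontally periodic luminance field covering the full
#' 360 degrees of azimuth and (by default) about +/- 35 degrees of elevation,
#' with the horizon at the centre. Rows run from the highest elevation (top)
#' to the lowest; columns run along azimuth. Luminance is linear (not
#' gamma-encoded) and in arbitrary non-negative units.
#'
#' @param luminance numeric matrix of non-negative, finite luminance values
#'   (rows = elevation, columns = azimuth).
#' @param deg_per_pixel angular resolution in degrees per pixel, identical for
#'   both axes.
#' @param elevation_range length-2 numeric, `c(min, max)` elevation in degrees
#'   with 0 at the horizon. Must equal `nrow(luminance) * deg_per_pixel` in
#'   span.
#' @param periodic_azimuth logical; full panoramas wrap seamlessly in azimuth,
#'   in which case `ncol(luminance) * deg_per_pixel` must be 360.
#'
#' @return An object of class `"panorama"`: a list with elements `luminance`,
#'   `deg_per_pixel`, `elevation_range`, `periodic_azimuth`.
#' @seealso [generate_natural_panorama()], [generate_sine_panorama()],
#'   [generate_step_panorama()], [rms_contrast()]
#' @export
panorama <- function(luminance, deg_per_pixel, elevation_range,
                     periodic_azimuth = TRUE) {
  if (!is.matrix(luminance) || !is.numeric(luminance))
    stop("'luminance' must be a numeric matrix")
  if (anyNA(luminance) || any(!is.finite(luminance)))
    stop("luminance values must be finite")
  if (any(luminance < 0))
    stop("luminance values must be non-negative")
  if (!is.numeric(deg_per_pixel) || length(deg_per_pixel) != 1L ||
      deg_per_pixel <= 0)
    stop("'deg_per_pixel' must be a single positive number")
  if (length(elevation_range) != 2L || diff(elevation_range) <= 0)
    stop("'elevation_range' must be c(min, max) with min < max")
  span <- ncol(luminance) * deg_per_pixel
  if (periodic_azimuth && abs(span - 360) > 1e-9)
    stop("periodic panorama must span 360 degrees of azimuth (got ",
         span, ")")
  espan <- nrow(luminance) * deg_per_pixel
  if (abs(espan - diff(elevation_range)) > 1e-9)
    stop("elevation range inconsistent with image height and resolution")
  structure(
    list(luminance = luminance,
         deg_per_pixel = deg_per_pixel,
         elevation_range = as.numeric(elevation_range),
         periodic_azimuth = isTRUE(periodic_azimuth)),
    class = "panorama")
}

#' @export
print.panorama <- function(x, ...) {
  L <- x$luminance
  cat("Panorama: ", nrow(L), " x ", ncol(L), " px at ",
      x$deg_per_pixel, " deg/px\n", sep = "")
  cat("  elevation ", x$elevation_range[1], " to ", x$elevation_range[2],
      " deg; azimuth ", if (x$periodic_azimuth) "0-360 deg (periodic)"
      else paste0(ncol(L) * x$deg_per_pixel, " deg (open)"), "\n", sep = "")
  cat(sprintf("  mean luminance %.4g, RMS contrast %.4g\n",
              mean(L), rms_contrast(x)))
  invisible(x)
}

#' @export
plot.panorama <- function(x, main = "panorama", ...) {
  L <- x$luminance
  az <- (seq_len(ncol(L)) - 0.5) * x$deg_per_pixel
  el <- x$elevation_range[2] - (seq_len(nrow(L)) - 0.5) * x$deg_per_pixel
  graphics::image(az, rev(el), t(L[nrow(L):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  xlab = "azimuth (deg)", ylab = "elevation (deg)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Pixel-centre coordinates of a panorama
#'
#' @param p a [panorama()].
#' @return list with `azimuth` (column centres, degrees, starting at 0) and
#'   `elevation` (row centres, degrees, top row first).
#' @export
panorama_coords <- function(p) {
  stopifnot(inherits(p, "panorama"))
  list(azimuth = (seq_len(ncol(p$luminance)) - 1) * p$deg_per_pixel,
       elevation = p$elevation_range[2] -
         (seq_len(nrow(p$luminance)) - 0.5) * p$deg_per_pixel)
}

#' Specification for synthetic natural-statistics panoramas
#'
#' Describes the target statistics of a synthetic panorama standing in for
#' photographed natural scenes: a broadband 1/f^beta spatial amplitude
#' spectrum, a low-contrast upper half ("sky") and a high-contrast lower half
#' ("ground"), and an adjustable global RMS contrast.
#'
#' @param width_px,height_px raster size in pixels. The default 2880 x 560 at
#'   0.125 deg/px gives 10 px per 1.25-degree receptor spacing.
#' @param spectral_slope exponent beta of the 1/f^beta amplitude spectrum.
#' @param sky_ground_contrast_ratio target ratio of lower-half to upper-half
#'   RMS contrast.
#' @param target_rms_contrast target global RMS contrast (sd / mean).
#' @param mean_luminance target mean luminance (arbitrary linear units).
#' @param seed integer seed; identical seeds give bit-identical panoramas.
#' @param deg_per_pixel angular resolution; `width_px * deg_per_pixel` must
#'   be 360.
#' @return object of class `"synthesis_spec"`.
#' @export
synthesis_spec <- function(width_px = 2880L, height_px = 560L,
                           spectral_slope = 1, sky_ground_contrast_ratio = 3,
                           target_rms_contrast = 0.4, mean_luminance = 100,
                           seed = 1L, deg_per_pixel = 360 / width_px) {
  if (target_rms_contrast <= 0) stop("target_rms_contrast must be positive")
  if (mean_luminance <= 0) stop("mean_luminance must be positive")
  if (width_px %% 2L != 0L) stop("width_px must be even")
  if (sky_ground_contrast_ratio <= 0)
    stop("sky_ground_contrast_ratio must be positive")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 spectral_slope = spectral_slope,
                 sky_ground_contrast_ratio = sky_ground_contrast_ratio,
                 target_rms_contrast = target_rms_contrast,
                 mean_luminance = mean_luminance,
                 seed = as.integer(seed),
                 deg_per_pixel = deg_per_pixel),
            class = "synthesis_spec")
}

#' Generate a synthetic natural-statistics panorama
#'
#' Shapes Gaussian white noise to a 1/f^beta amplitude spectrum in the 2D
#' Fourier domain (which guarantees exact horizontal wraparound), reweights
#' the upper and lower half-fields so that the ground is more contrasted than
#' the sky, then clips at zero and rescales iteratively until the requested
#' global RMS contrast, sky/ground contrast ratio and mean luminance are met.
#'
#' @param spec a [synthesis_spec()].
#' @return a [panorama()].
#' @export
generate_natural_panorama <- function(spec) {
  stopifnot(inherits(spec, "synthesis_spec"))
  W <- spec$width_px; H <- spec$height_px
  beta <- spec$spectral_slope
  r <- spec$sky_ground_contrast_ratio
  Ctar <- spec$target_rms_contrast
  mu <- spec$mean_luminance

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  z <- matrix(stats::rnorm(H * W), H, W)
  fy <- fft_freq(H); fx <- fft_freq(W)
  f <- sqrt(outer(fy^2, fx^2, `+`))
  amp <- ifelse(f > 0, f^(-beta), 0)     # kill DC; fluctuations only
  z <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / (H * W)
  z <- z / stats::sd(c(z))

  top <- seq_len(H %/% 2L)
  bot <- setdiff(seq_len(H), top)
  # per-half target sd of fluctuations: equal half means ~= mu, so
  # sd_total^2 ~= (sd_u^2 + sd_l^2)/2 with sd_l = r * sd_u
  sd_u <- Ctar * mu * sqrt(2 / (1 + r^2))
  sd_l <- r * sd_u
  gu <- sd_u / stats::sd(c(z[top, ])); gl <- sd_l / stats::sd(c(z[bot, ]))
  L <- z
  for (it in 1:25) {
    L[top, ] <- mu + gu * z[top, ]
    L[bot, ] <- mu + gl * z[bot, ]
    L[L < 0] <- 0
    L <- L * (mu / mean(L))
    cu <- stats::sd(c(L[top, ])) / mean(L[top, ])
    cl <- stats::sd(c(L[bot, ])) / mean(L[bot, ])
    Cg <- stats::sd(c(L)) / mean(L)
    if (abs(Cg / Ctar - 1) < 0.005 && abs((cl / cu) / r - 1) < 0.02) break
    # zero-clipping damps the achieved contrast and shifts the half means;
    # correct the half-contrast ratio and the global level separately
    rho <- (cl / cu) / r
    gu <- gu * sqrt(rho) * (Ctar / Cg)
    gl <- gl / sqrt(rho) * (Ctar / Cg)
  }
  panorama(L, spec$deg_per_pixel,
           c(-H / 2, H / 2) * spec$deg_per_pixel, TRUE)
}

#' Generate a sinusoidal grating panorama
#'
#' Luminance varies sinusoidally along azimuth,
#' `L(phi) = mean * (1 + contrast * sin(2 * pi * phi / lambda))`, and is
#' constant over elevation. Used as an analytic fixture: its RMS contrast is
#' `contrast / sqrt(2)` in closed form.
#'
#' @param spatial_wavelength_deg grating wavelength lambda in degrees;
#'   `360 / lambda` must be an integer so the grating wraps.
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param mean_luminance mean luminance (positive).
#' @param width_px,height_px,deg_per_pixel raster geometry.
#' @return a [panorama()].
#' @export
generate_sine_panorama <- function(spatial_wavelength_deg, contrast = 0.5,
                                   mean_luminance = 100,
                                   width_px = 2880L, height_px = 560L,
                                   deg_per_pixel = 360 / width_px) {
  ncyc <- 360 / spatial_wavelength_deg
  if (abs(ncyc - round(ncyc)) > 1e-9)
    stop("360 / spatial_wavelength_deg must be an integer for periodicity")
  if (contrast < 0 || contrast > 1) stop("contrast must lie in [0, 1]")
  if (mean_luminance <= 0) stop("mean_luminance must be positive")
  az <- (seq_len(width_px) - 1) * deg_per_pixel
  row <- mean_luminance *
    (1 + contrast * sin(2 * pi * az / spatial_wavelength_deg))
  L <- matrix(row, height_px, width_px, byrow = TRUE)
  panorama(L, deg_per_pixel,
           c(-height_px / 2, height_px / 2) * deg_per_pixel, TRUE)
}

#' Generate a two-level step panorama
#'
#' A panorama taking the value `high` inside an azimuthal band and `low`
#' outside it; periodicity forces exactly one rising and one falling edge.
#'
#' @param edge_azimuth_deg azimuth of the rising edge in degrees.
#' @param low,high the two luminance levels (non-negative).
#' @param band_width_deg azimuthal width of the `high` band.
#' @param width_px,height_px,deg_per_pixel raster geometry.
#' @return a [panorama()].
#' @export
generate_step_panorama <- function(edge_azimuth_deg = 180, low = 10,
                                   high = 100, band_width_deg = 90,
                                   width_px = 2880L, height_px = 560L,
                                   deg_per_pixel = 360 / width_px) {
  if (low < 0 || high < 0) stop("levels must be non-negative")
  az <- (seq_len(width_px) - 1) * deg_per_pixel
  rel <- (az - edge_azimuth_deg) %% 360
  row <- ifelse(rel < band_width_deg, high, low)
  L <- matrix(row, height_px, width_px, byrow = TRUE)
  panorama(L, deg_per_pixel,
           c(-height_px / 2, height_px / 2) * deg_per_pixel, TRUE)
}

#' Write / read a panorama
#'
#' The native format is a raw little-endian float64 array (`.bin`) plus a JSON
#' sidecar (`<path>.json`) recording dimensions, angular resolution and
#' elevation range; the round trip is bit-exact. If the `tiff` package is
#' available, paths ending in `.tif`/`.tiff` are written as single-channel
#' 32-bit float TIFF instead (lossy for float64 data).
#'
#' @param p a [panorama()].
#' @param path file path; the sidecar is written next to it.
#' @return `write_panorama` returns `path` invisibly; `read_panorama` returns
#'   a [panorama()].
#' @export
write_panorama <- function(p, path) {
  stopifnot(inherits(p, "panorama"))
  L <- p$luminance
  meta <- list(rows = nrow(L), cols = ncol(L),
               deg_per_pixel = p$deg_per_pixel,
               elevation_range = p$elevation_range,
               periodic_azimuth = p$periodic_azimuth,
               storage = "float64-le-colmajor")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF panoramas")
    meta$storage <- "float32-tiff"
    sc <- max(L)
    meta$tiff_scale <- sc
    tiff::writeTIFF(L / sc, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(L), con, size = 8L, endian = "little")
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_panorama
#' @export
read_panorama <- function(path) {
  mpath <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(mpath))
    stop("panorama file or JSON sidecar not found: ", path)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (identical(meta$storage, "float32-tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF panoramas")
    L <- tiff::readTIFF(path) * meta$tiff_scale
  } else {
    n <- meta$rows * meta$cols
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = n, size = 8L, endian = "little")
    if (length(v) != n) stop("panorama file truncated: ", path)
    L <- matrix(v, meta$rows, meta$cols)
  }
  panorama(L, meta$deg_per_pixel, meta$elevation_range,
           meta$periodic_azimuth)
}

# frequency coordinates of an unshifted DFT, in cycles per sample
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
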