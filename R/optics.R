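#' Front-end (optics and lamina) parameters
#'
#' Parameters of the peripheral processing stage shared by all detector
#' variants: Gaussian ommatidial optics, static Naka-Rushton
#' phototransduction and band-pass temporal filtering by lamina monopolar
#' cells (LMCs).
#'
#' @param delta_rho ommatidial acceptance angle in degrees (full width at
#'   half maximum of the Gaussian angular sensitivity). Default 1.64.
#' @param a_nr Naka-Rushton exponent. Default 0.7.
#' @param I0 mid-response intensity; `NULL` means "estimate per image as the
#'   geometric mean of its luminance" (see [estimate_I0()]).
#' @param tau_L LMC low-pass time constant, ms. Default 8.
#' @param tau_H LMC high-pass time constant, ms. Default 400.
#' @param dt simulation step, ms. Default 1 (1 kHz).
#' @return object of class `"optics_params"`.
#' @export
optics_params <- function(delta_rho = 1.64, a_nr = 0.7, I0 = NULL,
                          tau_L = 8, tau_H = 400, dt = 1) {
  if (tau_L <= 0 || tau_H <= 0 || dt <= 0)
    stop("time constants and dt must be positive")
  if (dt > min(tau_L, tau_H) / 2)
    stop("dt must be well below the smallest time constant")
  structure(list(delta_rho = delta_rho, a_nr = a_nr, I0 = I0,
                 tau_L = tau_L, tau_H = tau_H, dt = dt),
            class = "optics_params")
}

#' Photoreceptor sampling grid
#'
#' Rectangular grid of photoreceptor viewing directions with uniform
#' inter-receptor angle `phi` (1.25 degrees by default), covering the full
#' 360-degree azimuthal ring. Rows are ordered from the highest elevation
#' down. The default 56-row grid spans -34.375 to +34.375 degrees; a subset
#' of `n_elev` rows is picked centred on the horizon.
#'
#' @param n_elev number of elevation rows; `NULL` (default) takes the full
#'   grid.
#' @param phi inter-receptor angle in degrees; `360 / phi` must be integer.
#' @param elevation_of_row optional explicit per-row elevations (degrees,
#'   decreasing); overrides `n_elev`.
#' @return object of class `"receptor_grid"` with fields `phi`, `n_az`,
#'   `n_elev`, `elevation_of_row`, `azimuth_of_col`.
#' @export
receptor_grid <- function(n_elev = NULL, phi = 1.25,
                          elevation_of_row = NULL) {
  n_az <- 360 / phi
  if (abs(n_az - round(n_az)) > 1e-9)
    stop("360 / phi must be an integer for a periodic ring")
  n_az <- as.integer(round(n_az))
  if (is.null(elevation_of_row)) {
    n_full <- 56L
    full <- 35 - (seq_len(n_full) - 0.5) * 1.25
    if (abs(phi - 1.25) > 1e-9) {
      n_full <- as.integer(floor(70 / phi))
      full <- (n_full / 2) * phi - (seq_len(n_full) - 0.5) * phi
    }
    if (is.null(n_elev)) n_elev <- n_full
    if (n_elev > n_full) stop("n_elev exceeds the full grid (", n_full, ")")
    idx <- centred_indices(n_full, n_elev)
    elevation_of_row <- full[idx]
  }
  if (is.unsorted(rev(elevation_of_row), strictly = TRUE))
    stop("elevation_of_row must be strictly decreasing (top row first)")
  structure(list(phi = phi, n_az = n_az,
                 n_elev = length(elevation_of_row),
                 elevation_of_row = elevation_of_row,
                 azimuth_of_col = (seq_len(n_az) - 1) * phi),
            class = "receptor_grid")
}

# pick k consecutive indices out of 1..n centred on the middle; when parity
# forces an off-centre choice, round toward the lower (equatorial) side
centred_indices <- function(n, k) {
  start <- floor((n - k) / 2) + 1L + ((n - k) %% 2L)
  seq.int(start, length.out = k)
}

#' @export
print.receptor_grid <- function(x, ...) {
  cat("Receptor grid: ", x$n_elev, " rows x ", x$n_az,
      " azimuthal receptors (phi = ", x$phi, " deg)\n", sep = "")
  cat(sprintf("  elevations %.4g to %.4g deg\n",
              x$elevation_of_row[1], x$elevation_of_row[x$n_elev]))
  invisible(x)
}

#' Gaussian spatial low-pass (ommatidial optics)
#'
#' Blurs a panorama with an isotropic Gaussian whose full width at half
#' maximum equals the acceptance angle `delta_rho`
#' (`sigma = delta_rho / (2 * sqrt(2 * log(2)))`). Azimuth is convolved
#' circularly (via the FFT, so the wraparound is exact and the azimuthal mean
#' is conserved exactly); elevation uses edge replication.
#'
#' @param p a [panorama()].
#' @param delta_rho acceptance angle in degrees.
#' @return the blurred [panorama()].
#' @export
gaussian_prefilter <- function(p, delta_rho = 1.64) {
  stopifnot(inherits(p, "panorama"))
  if (p$deg_per_pixel > delta_rho / 4)
    stop("panorama resolution too coarse for delta_rho (aliasing risk): ",
         "need <= ", delta_rho / 4, " deg/px")
  sigma_px <- delta_rho / (2 * sqrt(2 * log(2))) / p$deg_per_pixel
  R <- ceiling(5 * sigma_px)
  g <- stats::dnorm(-R:R, sd = sigma_px)
  g <- g / sum(g)
  L <- p$luminance
  H <- nrow(L); W <- ncol(L)
  # elevation: replicate-pad then accumulate shifted rows
  Lp <- rbind(L[rep(1L, R), , drop = FALSE], L,
              L[rep(H, R), , drop = FALSE])
  out <- matrix(0, H, W)
  for (j in seq_along(g))
    out <- out + g[j] * Lp[(j - 1L) + seq_len(H), , drop = FALSE]
  # azimuth: exact circular convolution via FFT per row
  k <- numeric(W)
  k[((-R:R) %% W) + 1L] <- k[((-R:R) %% W) + 1L] + g
  kf <- stats::fft(k)
  outf <- stats::mvfft(t(out))
  out <- t(Re(stats::mvfft(outf * kf, inverse = TRUE)) / W)
  out[out < 0] <- 0  # FFT round-off can dip microscopically below zero
  panorama(out, p$deg_per_pixel, p$elevation_range, p$periodic_azimuth)
}

#' Sample a panorama at receptor positions
#'
#' Returns the luminance seen by each receptor when the image has been
#' displaced horizontally by `azimuth_offset_deg`: receptor `(row, col)`
#' reads the image at `(elevation_of_row, azimuth_of_col - offset)` by
#' bilinear interpolation, with azimuth wrapped modulo 360. Positive offsets
#' therefore displace the image toward increasing azimuth (the preferred
#' direction).
#'
#' @param p a (typically prefiltered) [panorama()].
#' @param grid a [receptor_grid()] whose elevations lie inside the panorama.
#' @param azimuth_offset_deg horizontal image displacement in degrees.
#' @return numeric matrix `n_elev x n_az` of luminance values.
#' @export
sample_receptors <- function(p, grid, azimuth_offset_deg = 0) {
  prof <- receptor_row_profiles(p, grid)
  idx <- azimuth_sample_index(grid$azimuth_of_col - azimuth_offset_deg,
                              p$deg_per_pixel, ncol(p$luminance))
  out <- prof[, idx$i0, drop = FALSE] * rep(1 - idx$f, each = nrow(prof)) +
    prof[, idx$i1, drop = FALSE] * rep(idx$f, each = nrow(prof))
  dimnames(out) <- NULL
  out
}

# per-receptor-row azimuthal luminance profiles: the elevation part of the
# bilinear interpolation is time-independent, so blend the two bracketing
# pixel rows once
receptor_row_profiles <- function(p, grid) {
  stopifnot(inherits(p, "panorama"), inherits(grid, "receptor_grid"))
  H <- nrow(p$luminance)
  emax <- p$elevation_range[2]
  rr <- (emax - grid$elevation_of_row) / p$deg_per_pixel + 0.5
  if (any(rr < 0.5 - 1e-9) || any(rr > H + 0.5 + 1e-9))
    stop("receptor grid exceeds the panorama elevation range")
  i0 <- pmin(pmax(floor(rr), 1L), H)
  f <- rr - i0
  i1 <- pmin(i0 + 1L, H)
  f[i0 == H] <- 0
  p$luminance[i0, , drop = FALSE] * (1 - f) +
    p$luminance[i1, , drop = FALSE] * f
}

azimuth_sample_index <- function(az_deg, deg_per_pixel, W) {
  x <- (az_deg / deg_per_pixel) %% W        # continuous column, 0-based
  i0 <- floor(x)
  f <- x - i0
  list(i0 = as.integer(i0 %% W) + 1L,
       i1 = as.integer((i0 + 1) %% W) + 1L,
       f = f)
}

#' Naka-Rushton phototransduction
#'
#' Static saturating transduction `u = I^a / (I^a + I0^a)`: monotone,
#' bounded in `[0, 1)`, half-maximal at `I = I0`. Mimics the logarithmic
#' luminance dependence of photoreceptors around a working point adapted to
#' the scene.
#'
#' @param I luminance (non-negative, any shape).
#' @param I0 mid-response intensity (positive scalar).
#' @param a exponent setting the slope at the working point. Default 0.7.
#' @return receptor potential, same shape as `I`.
#' @export
naka_rushton <- function(I, I0, a = 0.7) {
  if (any(I < 0)) stop("luminance must be non-negative")
  if (I0 <= 0) stop("I0 must be positive")
  Ia <- I^a
  Ia / (Ia + I0^a)
}

#' Estimate the mid-response intensity of a scene
#'
#' Geometric mean of the panorama luminance, `exp(mean(log(max(L, eps))))`
#' with `eps = 1e-6 * mean(L)` guarding zero pixels. Used as the per-image
#' Naka-Rushton working point `I0`.
#'
#' @param p a [panorama()] or a non-negative numeric array.
#' @return positive scalar.
#' @export
estimate_I0 <- function(p) {
  L <- if (inherits(p, "panorama")) p$luminance else p
  if (any(L < 0)) stop("luminance must be non-negative")
  m <- mean(L)
  if (m <= 0) stop("cannot estimate I0 of an all-zero image")
  exp(mean(log(pmax(L, 1e-6 * m))))
}

#' Recursive first-order temporal filters
#'
#' Exact-exponential discretisations of first-order filters at step `dt`:
#' the low-pass update is `y <- y + alpha * (x - y)` with
#' `alpha = 1 - exp(-dt / tau)`; the high-pass is the exact complement
#' `x - LP(x)`, so `LP + HP` reconstructs the input at every step. The LMC
#' band-pass is `LP(tau_L)` followed by `HP(tau_H)` in series.
#'
#' `filter_state()` creates the persistent state; the `*_step` functions
#' advance one sample and return `list(y, state)`; `lp_filter()` /
#' `hp_filter()` run a whole trace (initialised at its first sample, i.e.
#' assumed pre-adapted, unless `y0` is given).
#'
#' @param tau time constant, ms.
#' @param y0 initial state (low-pass output; defaults to the first input).
#' @param state a `filter_state()`.
#' @param x input sample (scalar or array) for step functions; numeric
#'   vector (time along the first axis) for trace functions.
#' @param dt step, ms.
#' @return step functions: `list(y = output, state = updated state)`;
#'   trace functions: numeric vector of outputs.
#' @name temporal_filters
NULL

#' @rdname temporal_filters
#' @export
filter_state <- function(tau, y0 = NULL) {
  if (tau < 0) stop("tau must be non-negative")
  structure(list(tau = tau, y_prev = y0), class = "filter_state")
}

lp_alpha <- function(tau, dt) if (tau <= 0) 1 else 1 - exp(-dt / tau)

#' @rdname temporal_filters
#' @export
lowpass_step <- function(state, x, dt) {
  if (is.null(state$y_prev)) state$y_prev <- x
  a <- lp_alpha(state$tau, dt)
  y <- state$y_prev + a * (x - state$y_prev)
  state$y_prev <- y
  list(y = y, state = state)
}

#' @rdname temporal_filters
#' @export
highpass_step <- function(state, x, dt) {
  r <- lowpass_step(state, x, dt)
  list(y = x - r$y, state = r$state)
}

#' @rdname temporal_filters
#' @export
lmc_bandpass_step <- function(state_L, state_H, x, dt) {
  r1 <- lowpass_step(state_L, x, dt)
  r2 <- highpass_step(state_H, r1$y, dt)
  list(y = r2$y, state_L = r1$state, state_H = r2$state)
}

#' @rdname temporal_filters
#' @export
lp_filter <- function(x, tau, dt, y0 = x[1]) {
  a <- lp_alpha(tau, dt)
  y <- numeric(length(x))
  prev <- y0
  for (t in seq_along(x)) {
    prev <- prev + a * (x[t] - prev)
    y[t] <- prev
  }
  y
}

#' @rdname temporal_filters
#' @export
hp_filter <- function(x, tau, dt, y0 = x[1]) x - lp_filter(x, tau, dt, y0)
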