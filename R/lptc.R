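#' Gain-control integration parameters
#'
#' Reversal potentials and leak conductance of the nonlinear dendritic
#' pooling stage. With the default unit values the membrane potential is
#' `Z = (S+ - S-) / (1 + S+ + S-)` where `S+`/`S-` are the weighted sums of
#' the rectified half-detector outputs.
#'
#' @param E_plus,E_minus depolarizing and hyperpolarizing reversal
#'   potentials (magnitudes). Defaults 1.
#' @param G0 leak conductance. Default 1.
#' @return object of class `"gain_control_params"`.
#' @export
gain_control_params <- function(E_plus = 1, E_minus = 1, G0 = 1) {
  if (G0 <= 0) stop("G0 must be positive")
  structure(list(E_plus = E_plus, E_minus = E_minus, G0 = G0),
            class = "gain_control_params")
}

#' Gain-control dendritic integration
#'
#' Pools weighted half-detector outputs into the model LPTC membrane
#' potential:
#' `Z = (sum(w * P+) * E+ - sum(w * P-) * E-) /
#'      (G0 + sum(w * P+) + sum(w * P-))`.
#' The summed conductances normalize the response for different stimulus
#' extents, so `|Z| < max(E+, E-)` always, and `Z` grows sublinearly with
#' the number of pooled sites. Weights enter both numerator and denominator
#' (they model synaptic density, i.e. conductance).
#'
#' @param P_plus,P_minus non-negative arrays of half-detector outputs (any
#'   congruent shape).
#' @param w weights in `[0, 1]`, same shape as `P_plus` (default all 1).
#' @param gc a [gain_control_params()].
#' @return scalar membrane potential `Z`.
#' @export
gain_control_integrate <- function(P_plus, P_minus, w = 1,
                                   gc = gain_control_params()) {
  if (length(P_plus) == 0) stop("empty receptive field")
  Sp <- sum(w * P_plus)
  Sm <- sum(w * P_minus)
  (Sp * gc$E_plus - Sm * gc$E_minus) / (gc$G0 + Sp + Sm)
}

#' Receptive fields over the EMD lattice
#'
#' A receptive field selects and weights the EMD sites pooled by a model
#' LPTC. Sites live on the lattice of `n_elev` rows times `n_az` azimuthal
#' EMD columns (site `k` correlates receptor columns `k` and `k + 1`, with
#' wraparound at the ring closure). `rect_rf()` builds a unit-weight
#' rectangle counted in *receptors*: `n` receptors horizontally give
#' `n - 1` EMD columns (the full ring, `n = n_az`, closes on itself and
#' gives `n_az` columns); `m` receptor rows give `m` EMD rows. Fields are
#' centred on the horizon and on the vertical axis of the image (azimuth
#' 180), rounding toward the equator/front when parity forces a choice.
#'
#' @param m number of receptor rows pooled.
#' @param n number of receptor columns pooled (2 .. `n_az`).
#' @param grid a [receptor_grid()].
#' @param centre_az azimuth (degrees) the field is centred on.
#' @return object of class `"receptive_field"`: list with the weight matrix
#'   `w` (`n_elev x n_az`, zero outside the field), the shape descriptor
#'   and the receptor/EMD counts.
#' @export
rect_rf <- function(m, n, grid, centre_az = 180) {
  stopifnot(inherits(grid, "receptor_grid"))
  if (m < 1 || m > grid$n_elev) stop("m out of range")
  if (n < 2 || n > grid$n_az) stop("n must be in 2..", grid$n_az)
  rows <- centred_indices(grid$n_elev, m)
  w <- matrix(0, grid$n_elev, grid$n_az)
  if (n == grid$n_az) {
    cols <- seq_len(grid$n_az)                     # closed ring
  } else {
    rec <- centred_receptor_cols(n, grid, centre_az)
    cols <- rec[-length(rec)]                      # site k = receptors k,k+1
  }
  w[rows, cols] <- 1
  structure(list(w = w, m = m, n = n,
                 n_sites = length(rows) * length(cols),
                 rows = rows, cols = cols,
                 centre = c(azimuth = centre_az,
                            elevation = mean(grid$elevation_of_row[rows])),
                 kind = "rect"),
            class = "receptive_field")
}

centred_receptor_cols <- function(n, grid, centre_az) {
  c0 <- which.min(abs(grid$azimuth_of_col - centre_az))
  idx <- centred_indices(grid$n_az, n) - (grid$n_az %/% 2L + 1L) + c0
  ((idx - 1L) %% grid$n_az) + 1L
}

#' @export
print.receptive_field <- function(x, ...) {
  cat("Receptive field (", x$kind, "): ", x$m, " x ", x$n,
      " receptors -> ", x$n_sites, " EMD sites",
      if (x$kind == "rect" && x$n == ncol(x$w)) " (closed ring)", "\n",
      sep = "")
  invisible(x)
}

#' HSE-cell weight-field parameters
#'
#' Centre and widths of the Gaussian sensitivity estimate of the HSE cell
#' (the equatorial horizontal-system LPTC): centre at azimuth -15 deg,
#' elevation +2 deg; vertical sigma 35 deg; horizontal sigma 120 deg on the
#' lateral side of the centre and 25 deg on the frontal side. Zero azimuth
#' is the frontal equatorial viewing direction.
#'
#' @param phi_c,theta_c centre azimuth and elevation, degrees.
#' @param sigma_elev vertical width, degrees.
#' @param sigma_az_lateral,sigma_az_frontal horizontal widths, degrees.
#' @return object of class `"hse_field_params"`.
#' @export
hse_field_params <- function(phi_c = -15, theta_c = 2, sigma_elev = 35,
                             sigma_az_lateral = 120, sigma_az_frontal = 25) {
  if (sigma_elev <= 0 || sigma_az_lateral <= 0 || sigma_az_frontal <= 0)
    stop("all sigmas must be positive")
  structure(list(phi_c = phi_c, theta_c = theta_c, sigma_elev = sigma_elev,
                 sigma_az_lateral = sigma_az_lateral,
                 sigma_az_frontal = sigma_az_frontal),
            class = "hse_field_params")
}

#' Gaussian HSE receptive field
#'
#' Graded weight field
#' `w(phi, theta) = exp(-((phi - phi_c)^2 / (2 sigma_az^2) +
#'                        (theta - theta_c)^2 / (2 sigma_elev^2)))`
#' with peak weight 1 at the centre, using the lateral sigma for azimuths on
#' the lateral side of the centre and the frontal sigma on the frontal side.
#' Azimuthal distance is taken on the circle (shortest arc); the grid's
#' azimuth convention (0..360, image centre at 180) is mapped so that 0
#' corresponds to the frontal equatorial direction.
#'
#' @param grid a [receptor_grid()].
#' @param params an [hse_field_params()].
#' @return a `"receptive_field"` with graded weights over all EMD sites.
#' @export
hse_rf <- function(grid, params = hse_field_params()) {
  stopifnot(inherits(grid, "receptor_grid"))
  # site azimuth: midpoint of the receptor pair, remapped so 0 = frontal
  site_az <- grid$azimuth_of_col + grid$phi / 2
  phi <- ((site_az - 180) + 180) %% 360 - 180      # signed, frontal at 0
  dphi <- (phi - params$phi_c + 180) %% 360 - 180  # shortest arc
  sig <- ifelse(dphi > 0, params$sigma_az_lateral, params$sigma_az_frontal)
  wa <- exp(-dphi^2 / (2 * sig^2))
  we <- exp(-(grid$elevation_of_row - params$theta_c)^2 /
              (2 * params$sigma_elev^2))
  w <- outer(we, wa)
  structure(list(w = w, m = grid$n_elev, n = grid$n_az,
                 n_sites = sum(w > 0), rows = seq_len(grid$n_elev),
                 cols = seq_len(grid$n_az),
                 centre = c(azimuth = params$phi_c,
                            elevation = params$theta_c),
                 kind = "hse"),
            class = "receptive_field")
}
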