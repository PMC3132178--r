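#' Elementary-motion-detector parameters
#'
#' Parameters of the correlator stage and of the four detector variants.
#' Every EMD correlates the low-pass-delayed signal of one receptor channel
#' with the undelayed signal of its nearest horizontal neighbour; the two
#' mirror-symmetric half-detectors are half-wave rectified into the
#' non-negative outputs `P+` (preferred direction, front-to-back /
#' increasing azimuth) and `P-` (null direction).
#'
#' Variants: `"basic"` — the plain correlator; `"adaptive"` — a first-order
#' high-pass filter in the cross (undelayed) arm whose time constant relaxes
#' toward `max_tauh` at rate `K` and is driven toward `min_tauh` by the rate
#' of change of the delayed arm's low-pass signal; `"saturation"` — a
#' `tanh(a_sat * s)` compressive nonlinearity on the detector input lines,
#' with `a_sat` calibrated so the 75th-percentile input magnitude maps to
#' `tanh(1)`; `"input_gain"` — each input line divided by its running mean
#' absolute deviation (full-wave rectification followed by a first-order
#' low-pass with time constant `tau_A`).
#'
#' @param variant one of `"basic"`, `"adaptive"`, `"saturation"`,
#'   `"input_gain"`.
#' @param tau_lp delay low-pass time constant, ms. Default 40.
#' @param min_tauh,max_tauh adaptive range of the cross-arm high-pass time
#'   constant, ms. Defaults 0 and 500.
#' @param K relaxation constant of the adaptation, per ms (0.1 kHz).
#' @param tau_S time constant of the low-pass smoothing the adaptation drive,
#'   ms. Default 500.
#' @param g_adapt gain mapping the smoothed drive to an adaptation rate;
#'   `NULL` means "calibrate per run so that half the dynamic range of the
#'   drive balances the relaxation at mid-range".
#' @param a_sat saturation scale; `NULL` means "calibrate per run from the
#'   75th percentiles of the preprocessed inputs" (see
#'   [estimate_saturation_gain()]).
#' @param tau_A gain-control averaging time constant, ms. Default 200.
#' @param eps_gain divisive guard; `NULL` means "1e-6 of the calibration
#'   signal scale".
#' @return object of class `"emd_params"`.
#' @export
emd_params <- function(variant = c("basic", "adaptive", "saturation",
                                   "input_gain"),
                       tau_lp = 40, min_tauh = 0, max_tauh = 500,
                       K = 0.1, tau_S = 500, g_adapt = NULL,
                       a_sat = NULL, tau_A = 200, eps_gain = NULL) {
  variant <- match.arg(variant)
  if (tau_lp <= 0) stop("tau_lp must be positive")
  if (min_tauh > max_tauh) stop("min_tauh must not exceed max_tauh")
  if (K <= 0) stop("K must be positive")
  if (tau_A <= 0) stop("tau_A must be positive")
  structure(list(variant = variant, tau_lp = tau_lp,
                 min_tauh = min_tauh, max_tauh = max_tauh, K = K,
                 tau_S = tau_S, g_adapt = g_adapt,
                 a_sat = a_sat, tau_A = tau_A, eps_gain = eps_gain),
            class = "emd_params")
}

#' Basic correlator half-detectors over a signal pair
#'
#' Reference implementation of one EMD on two preprocessed input traces:
#' `P+ = max(0, LP_tau_lp(left) * right)` and
#' `P- = max(0, left * LP_tau_lp(right))`, where `left` is the receptor at
#' the smaller azimuth. Motion from left toward right (increasing azimuth)
#' is the preferred direction.
#'
#' @param left,right numeric traces of the two input channels.
#' @param tau_lp delay time constant, ms.
#' @param dt step, ms.
#' @return list with traces `P_plus` and `P_minus`.
#' @export
basic_emd <- function(left, right, tau_lp = 40, dt = 1) {
  if (length(left) != length(right)) stop("traces must have equal length")
  Dl <- lp_filter(left, tau_lp, dt, y0 = left[1])
  Dr <- lp_filter(right, tau_lp, dt, y0 = right[1])
  list(P_plus = pmax(0, Dl * right), P_minus = pmax(0, left * Dr))
}

#' One step of the adaptive cross-arm time constant
#'
#' The high-pass time constant of the adaptive variant relaxes toward
#' `max_tauh` with rate `K` and is pulled toward `min_tauh` at a rate
#' proportional to the smoothed rate of change `S` of the delayed arm's
#' low-pass signal:
#' `d tau_h / dt = K * (max_tauh - tau_h) - g * S * (tau_h - min_tauh)`,
#' clamped to `[min_tauh, max_tauh]`. The linear ODE is integrated exactly
#' over each step (exponential update), so the iteration is stable for any
#' drive strength; the fixed point for constant `S` is
#' `(K * max_tauh + g * S * min_tauh) / (K + g * S)`.
#'
#' @param tau_h current time constant(s), ms.
#' @param S smoothed magnitude of the low-pass signal derivative (same
#'   shape as `tau_h`).
#' @param g adaptation gain.
#' @param dt step, ms.
#' @param params an [emd_params()] providing `K`, `min_tauh`, `max_tauh`.
#' @return updated `tau_h`, clamped to the adaptive range.
#' @export
update_tau_h <- function(tau_h, S, g, dt = 1, params = emd_params("adaptive")) {
  B <- params$K + g * S
  fp <- (params$K * params$max_tauh + g * S * params$min_tauh) / B
  tau_h <- fp + (tau_h - fp) * exp(-B * dt)
  pmin(pmax(tau_h, params$min_tauh), params$max_tauh)
}

#' Calibrate the input-saturation scale
#'
#' `a_sat = 1 / q75`, where `q75` is the mean over channels of each
#' channel's 75th percentile of absolute signal value over a calibration
#' window, so that a 75th-percentile input maps to `tanh(1)`. Homogeneous of
#' degree -1: scaling all signals by `k` scales `a_sat` by `1/k`, making
#' `tanh(a_sat * s)` invariant to the overall input scale.
#'
#' @param signals numeric matrix (time x channels) or vector of preprocessed
#'   input signals over the calibration window.
#' @return positive scalar `a_sat`.
#' @export
estimate_saturation_gain <- function(signals) {
  if (length(signals) == 0) stop("empty calibration window")
  if (!is.matrix(signals)) signals <- matrix(signals, ncol = 1)
  q <- apply(abs(signals), 2, stats::quantile, probs = 0.75, names = FALSE)
  qbar <- mean(q)
  if (qbar <= 0) stop("degenerate calibration window (all signals zero)")
  1 / qbar
}

#' Compressive input saturation
#'
#' `tanh(a_sat * s)`: odd, monotone, bounded in (-1, 1).
#'
#' @param s input signal (any shape).
#' @param a_sat saturation scale.
#' @return saturated signal, same shape as `s`.
#' @export
saturate_input <- function(s, a_sat) tanh(a_sat * s)

#' Divisive gain control of an input line
#'
#' Reference (whole-trace) implementation of the input-line gain control:
#' the mean absolute deviation of the signal is tracked as
#' `mad_t = LP_tau_A(|x_t|)` and the output is `x_t / (mad_t + eps)`.
#' For a settled periodic input the output amplitude is insensitive to the
#' input scale.
#'
#' @param x numeric input trace.
#' @param tau_A averaging time constant, ms.
#' @param dt step, ms.
#' @param eps divisive guard (small positive number).
#' @return normalized trace, same length as `x`.
#' @export
input_gain_control <- function(x, tau_A = 200, dt = 1, eps = 1e-9) {
  mad <- lp_filter(abs(x), tau_A, dt, y0 = abs(x[1]))
  x / (mad + eps)
}

#' Build an EMD field from receptor traces (reference path)
#'
#' Applies the selected detector variant to every nearest-neighbour pair of
#' a `time x rows x cols` array of preprocessed receptor signals. For an
#' open sub-array of `n` receptor columns this yields `n - 1` EMD columns;
#' with `periodic = TRUE` the last column pairs with the first, closing the
#' 360-degree ring (`n` EMD columns). This pure-R path is the oracle for
#' the compiled engine; production runs use [run_simulation()].
#'
#' @param receptor_field numeric array `time x rows x cols` (a matrix is
#'   treated as `time x 1 x cols`) of preprocessed (band-pass) signals.
#' @param params an [emd_params()]. Calibrated quantities (`a_sat`,
#'   `eps_gain`, `g_adapt`) must be set when the variant needs them; for the
#'   reference path they default to calibration over the whole input.
#' @param dt step, ms.
#' @param periodic close the azimuthal ring.
#' @return list of arrays `P_plus`, `P_minus` (`time x rows x n_emd`).
#' @export
build_emd_field <- function(receptor_field, params = emd_params(), dt = 1,
                            periodic = FALSE) {
  if (is.matrix(receptor_field))
    receptor_field <- array(receptor_field,
                            c(nrow(receptor_field), 1, ncol(receptor_field)))
  d <- dim(receptor_field)
  if (d[3] < 2) stop("need at least 2 receptor columns")
  Tn <- d[1]; m <- d[2]; nc <- d[3]
  n_emd <- if (periodic) nc else nc - 1L

  # per-channel variant preprocessing of the input lines
  s <- receptor_field
  if (params$variant == "saturation") {
    a_sat <- params$a_sat
    if (is.null(a_sat))
      a_sat <- estimate_saturation_gain(matrix(receptor_field, Tn))
    s[] <- saturate_input(receptor_field, a_sat)
  } else if (params$variant == "input_gain") {
    eps <- params$eps_gain
    if (is.null(eps)) eps <- 1e-6 * mean(abs(receptor_field))
    for (i in seq_len(m)) for (j in seq_len(nc))
      s[, i, j] <- input_gain_control(receptor_field[, i, j],
                                      params$tau_A, dt, eps)
  }

  # delay arm per channel
  D <- s
  for (i in seq_len(m)) for (j in seq_len(nc))
    D[, i, j] <- lp_filter(s[, i, j], params$tau_lp, dt, y0 = s[1, i, j])

  if (params$variant == "adaptive") {
    # smoothed magnitude of the delay-arm derivative, per channel
    S <- D
    for (i in seq_len(m)) for (j in seq_len(nc))
      S[, i, j] <- lp_filter(abs(c(0, diff(D[, i, j])) / dt),
                             params$tau_S, dt, y0 = 0)
    g <- params$g_adapt
    if (is.null(g)) {
      s_half <- 0.5 * stats::quantile(c(S), 0.95, names = FALSE)
      g <- if (s_half > 0) params$K / s_half else 0
    }
    # per-channel tau_h trajectory and, per direction, the cross-arm
    # high-pass of the *neighbouring* channel's signal with this tau_h
    tau_h <- array(0, dim(S))
    for (i in seq_len(m)) for (j in seq_len(nc)) {
      th <- params$max_tauh
      for (t in seq_len(Tn)) {
        th <- update_tau_h(th, S[t, i, j], g, dt, params)
        tau_h[t, i, j] <- th
      }
    }
    hp_with_tauh <- function(x, th_trace) {
      lp <- x[1]; out <- numeric(length(x))
      for (t in seq_along(x)) {
        a <- lp_alpha(th_trace[t], dt)
        lp <- lp + a * (x[t] - lp)
        out[t] <- x[t] - lp
      }
      out
    }
    P_plus <- array(0, c(Tn, m, n_emd))
    P_minus <- array(0, c(Tn, m, n_emd))
    for (k in seq_len(n_emd)) {
      kr <- if (k == nc) 1L else k + 1L
      for (i in seq_len(m)) {
        cr <- hp_with_tauh(s[, i, kr], tau_h[, i, k])   # P+ cross arm
        cl <- hp_with_tauh(s[, i, k], tau_h[, i, kr])   # P- cross arm
        P_plus[, i, k] <- pmax(0, D[, i, k] * cr)
        P_minus[, i, k] <- pmax(0, cl * D[, i, kr])
      }
    }
    return(list(P_plus = P_plus, P_minus = P_minus))
  }

  P_plus <- array(0, c(Tn, m, n_emd))
  P_minus <- array(0, c(Tn, m, n_emd))
  for (k in seq_len(n_emd)) {
    kr <- if (k == nc) 1L else k + 1L
    for (i in seq_len(m)) {
      P_plus[, i, k] <- pmax(0, D[, i, k] * s[, i, kr])
      P_minus[, i, k] <- pmax(0, s[, i, k] * D[, i, kr])
    }
  }
  list(P_plus = P_plus, P_minus = P_minus)
}
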