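#' Stimulus specification
#'
#' Constant-velocity horizontal rotation of the panorama in the preferred
#' direction. Defaults follow the standard acquisition protocol: 60 deg/s
#' for 12 s at 1 kHz (two full rotations), with the first 6 s (the first
#' rotation) discarded to exclude onset transients.
#'
#' @param velocity angular velocity, deg/s (positive = preferred direction).
#' @param duration total stimulation time, s.
#' @param dt simulation step, ms.
#' @param discard initial time discarded from the retained trace, s.
#' @return object of class `"stimulus_spec"`.
#' @export
stimulus_spec <- function(velocity = 60, duration = 12, dt = 1,
                          discard = 6) {
  if (duration <= discard || discard < 0)
    stop("need duration > discard >= 0")
  if (dt <= 0) stop("dt must be positive")
  structure(list(velocity = velocity, duration = duration, dt = dt,
                 discard = discard,
                 n_steps = as.integer(round(duration * 1000 / dt)),
                 n_discard = as.integer(round(discard * 1000 / dt))),
            class = "stimulus_spec")
}

#' Number of full image rotations a stimulus performs
#'
#' @param stim a [stimulus_spec()].
#' @return `abs(velocity) * duration / 360`.
#' @export
n_rotations <- function(stim) abs(stim$velocity) * stim$duration / 360

#' Model LPTC
#'
#' Bundles a detector variant, its parameters, the front-end parameters and
#' a receptive field into a simulatable model tangential cell. Use
#' [simulate()] (or [run_simulation()] directly) to drive it with a moving
#' panorama.
#'
#' @param variant detector variant, see [emd_params()].
#' @param rf a `"receptive_field"` (see [rect_rf()], [hse_rf()]), or `NULL`
#'   to be supplied at simulation time.
#' @param grid the [receptor_grid()] the receptive field lives on.
#' @param optics an [optics_params()].
#' @param emd an [emd_params()]; its `variant` is overridden by `variant`.
#' @param gain a [gain_control_params()].
#' @return object of class `"lptc_model"`.
#' @export
lptc_model <- function(variant = c("basic", "adaptive", "saturation",
                                   "input_gain"),
                       rf = NULL, grid = receptor_grid(),
                       optics = optics_params(), emd = emd_params(),
                       gain = gain_control_params()) {
  variant <- match.arg(variant)
  emd$variant <- variant
  structure(list(variant = variant, rf = rf, grid = grid, optics = optics,
                 emd = emd, gain = gain),
            class = "lptc_model")
}

#' @export
print.lptc_model <- function(x, ...) {
  cat("Model LPTC (", x$variant, " EMD variant)\n", sep = "")
  cat("  grid: ", x$grid$n_elev, " x ", x$grid$n_az, " receptors (phi = ",
      x$grid$phi, " deg)\n", sep = "")
  if (!is.null(x$rf)) {
    cat("  "); print(x$rf)
  } else cat("  receptive field: supplied at simulation time\n")
  cat("  tau_lp ", x$emd$tau_lp, " ms; LMC tau_L ", x$optics$tau_L,
      " ms, tau_H ", x$optics$tau_H, " ms; Naka-Rushton a ",
      x$optics$a_nr, "\n", sep = "")
  invisible(x)
}

#' @export
summary.lptc_model <- function(object, ...) {
  print(object)
  cat("Gain control: E+ ", object$gain$E_plus, ", E- ", object$gain$E_minus,
      ", G0 ", object$gain$G0, "\n", sep = "")
  if (object$variant == "adaptive")
    cat("Adaptation: tau_h in [", object$emd$min_tauh, ", ",
        object$emd$max_tauh, "] ms, K ", object$emd$K, " /ms, tau_S ",
        object$emd$tau_S, " ms\n", sep = "")
  if (object$variant == "saturation")
    cat("Saturation scale a_sat: ",
        if (is.null(object$emd$a_sat)) "calibrated per run"
        else object$emd$a_sat, "\n", sep = "")
  if (object$variant == "input_gain")
    cat("Input gain control: tau_A ", object$emd$tau_A, " ms\n", sep = "")
  invisible(object)
}

#' Simulate an LPTC model response
#'
#' [stats::simulate()] method: drives the model with a horizontally moving
#' panorama. The pipeline is fully deterministic given its inputs, so
#' `nsim`/`seed` only matter when `panorama` is a [synthesis_spec()], in
#' which case `nsim` fresh panoramas (seeds `seed`, `seed + 1`, ...) are
#' generated and simulated.
#'
#' @param object an [lptc_model()].
#' @param nsim number of synthetic panoramas (ignored for a fixed panorama).
#' @param seed base seed for synthetic panoramas.
#' @param panorama a [panorama()] or a [synthesis_spec()].
#' @param stimulus a [stimulus_spec()].
#' @param ... unused.
#' @return a single `"lptc_response"`, or a list of them when `nsim > 1`.
#' @export
simulate.lptc_model <- function(object, nsim = 1, seed = NULL,
                                panorama, stimulus = stimulus_spec(), ...) {
  if (is.null(object$rf)) stop("model has no receptive field")
  if (inherits(panorama, "synthesis_spec")) {
    if (is.null(seed)) seed <- panorama$seed
    out <- lapply(seq_len(nsim), function(i) {
      panorama$seed <- seed + i - 1L
      p <- generate_natural_panorama(panorama)
      run_simulation(p, object$variant, list(object$rf), stimulus,
                     grid = object$grid, optics = object$optics,
                     emd = object$emd, gain = object$gain)[[1]]
    })
    if (nsim == 1) out[[1]] else out
  } else {
    run_simulation(panorama, object$variant, list(object$rf), stimulus,
                   grid = object$grid, optics = object$optics,
                   emd = object$emd, gain = object$gain)[[1]]
  }
}

#' Run the full stimulus-response loop
#'
#' Drives the front end (Gaussian optics, Naka-Rushton, LMC band-pass), the
#' selected EMD variant over the full azimuthal ring of the receptor grid,
#' and gain-control integration for every receptive field in `rf_list`, at
#' the stimulus sample rate. All receptive fields share one front-end/EMD
#' pass; the per-site half-detector outputs are reduced into per-field sums
#' at each step (streaming, nothing per-site is stored over time). The
#' retained traces exclude the first `discard` seconds.
#'
#' Variants needing run-time calibration (saturation scale, input-gain
#' guard, adaptation gain) are calibrated on the discarded first rotation.
#'
#' @param p a periodic [panorama()] (prefiltered internally).
#' @param variant detector variant.
#' @param rf_list list of `"receptive_field"` objects on `grid`.
#' @param stim a [stimulus_spec()].
#' @param grid a [receptor_grid()].
#' @param optics an [optics_params()].
#' @param emd an [emd_params()] (variant overridden).
#' @param gain a [gain_control_params()].
#' @param prefiltered set `TRUE` if `p` has already been through
#'   [gaussian_prefilter()] (saves recomputation across calls).
#' @return list of `"lptc_response"` objects, one per receptive field.
#' @export
run_simulation <- function(p, variant, rf_list, stim = stimulus_spec(),
                           grid = receptor_grid(),
                           optics = optics_params(),
                           emd = emd_params(), gain = gain_control_params(),
                           prefiltered = FALSE) {
  stopifnot(inherits(p, "panorama"))
  if (!p$periodic_azimuth)
    stop("run_simulation requires a periodic panorama")
  if (!is.list(rf_list) || !all(vapply(rf_list, inherits, TRUE,
                                       "receptive_field")))
    stop("rf_list must be a list of receptive_field objects")
  emd$variant <- variant
  for (rf in rf_list)
    if (!all(dim(rf$w) == c(grid$n_elev, grid$n_az)))
      stop("receptive field does not match the receptor grid")

  pf <- if (prefiltered) p else gaussian_prefilter(p, optics$delta_rho)
  prof <- receptor_row_profiles(pf, grid)
  I0 <- if (is.null(optics$I0)) estimate_I0(p) else optics$I0
  cal <- calibrate_variant(prof, pf$deg_per_pixel, grid, stim, optics, I0,
                           emd)

  Z <- cpp_run_engine(prof, pf$deg_per_pixel, grid$azimuth_of_col,
                      stim$velocity, stim$dt, stim$n_steps,
                      I0, optics$a_nr, optics$tau_L, optics$tau_H,
                      emd$tau_lp, variant_code(variant),
                      cal$a_sat, cal$eps_gain, emd$tau_A,
                      emd$min_tauh, emd$max_tauh, emd$K, cal$g_adapt,
                      emd$tau_S,
                      lapply(rf_list, `[[`, "w"),
                      gain$E_plus, gain$E_minus, gain$G0)
  keep <- seq.int(stim$n_discard + 1L, stim$n_steps)
  t_ms <- (keep - 1L) * stim$dt
  lapply(seq_along(rf_list), function(i) {
    structure(list(Z = Z[keep, i], t_ms = t_ms, dt = stim$dt,
                   variant = variant, rf = rf_list[[i]], stimulus = stim,
                   calibration = cal, I0 = I0),
              class = "lptc_response")
  })
}

variant_code <- function(variant) {
  match(variant, c("basic", "adaptive", "saturation", "input_gain")) - 1L
}

# calibrate run-time constants on the (to-be-discarded) first rotation:
# a_sat (saturation), eps_gain (input gain guard), g_adapt (adaptation gain)
calibrate_variant <- function(prof, deg_per_pixel, grid, stim, optics, I0,
                              emd) {
  out <- list(a_sat = if (is.null(emd$a_sat)) 0 else emd$a_sat,
              eps_gain = if (is.null(emd$eps_gain)) 0 else emd$eps_gain,
              g_adapt = if (is.null(emd$g_adapt)) 0 else emd$g_adapt)
  need_sat <- emd$variant == "saturation" && is.null(emd$a_sat)
  need_eps <- emd$variant == "input_gain" && is.null(emd$eps_gain)
  need_g <- emd$variant == "adaptive" && is.null(emd$g_adapt)
  if (!(need_sat || need_eps || need_g)) return(out)

  rot_steps <- if (stim$velocity != 0)
    round(360 / abs(stim$velocity) * 1000 / stim$dt) else stim$n_discard
  n_cal <- as.integer(min(max(rot_steps, 1000), stim$n_steps))
  stride <- 4L
  cal <- cpp_frontend_calib(prof, deg_per_pixel, grid$azimuth_of_col,
                            stim$velocity, stim$dt, n_cal, stride,
                            I0, optics$a_nr, optics$tau_L, optics$tau_H,
                            emd$tau_lp, emd$tau_S)
  if (need_sat)
    out$a_sat <- estimate_saturation_gain(cal$abs_bp)
  if (need_eps) {
    sc <- mean(cal$abs_bp)
    out$eps_gain <- 1e-6 * max(sc, .Machine$double.eps)
  }
  if (need_g) {
    s_half <- 0.5 * stats::quantile(c(cal$S), 0.95, names = FALSE)
    out$g_adapt <- if (s_half > 0) emd$K / s_half else 0
  }
  out
}

#' @export
print.lptc_response <- function(x, ...) {
  cat("LPTC response (", x$variant, " variant): ", length(x$Z),
      " retained samples at dt = ", x$dt, " ms\n", sep = "")
  cat(sprintf("  mean Z %.5g, sd %.5g, range [%.5g, %.5g]\n",
              mean(x$Z), stats::sd(x$Z), min(x$Z), max(x$Z)))
  invisible(x)
}

#' @export
plot.lptc_response <- function(x, normalized = FALSE, ...) {
  y <- if (normalized) normalize_response(x) else x$Z
  graphics::plot(x$t_ms / 1000, y, type = "l",
                 xlab = "time (s)",
                 ylab = if (normalized) "normalized response N"
                 else "membrane potential Z", ...)
  graphics::abline(h = if (normalized) 0 else mean(x$Z), lty = 3)
  invisible(x)
}

#' Sweep modulation SD over receptive-field geometries
#'
#' `sweep_rf_1d()` measures the pattern-dependent modulation SD of
#' one-row (1 x n receptor) arrays for every elevation row and horizontal
#' extent requested; `sweep_rf_2d()` does the same for m x n rectangles
#' centred on the horizon. Each sweep runs the front end and EMD field once
#' per (panorama, variant) and integrates all receptive fields post hoc;
#' the full-field reference of the modulation SD is the closed ring over
#' all rows simulated in that sweep.
#'
#' @param p a periodic [panorama()].
#' @param variant detector variant.
#' @param elevation_rows integer indices (into `grid$elevation_of_row`) of
#'   the rows to sweep, for the 1-D sweep.
#' @param m_list,n_list ascending receptor counts (vertical, horizontal).
#' @param stim a [stimulus_spec()].
#' @param grid a [receptor_grid()] (its rows bound the sweep).
#' @param ... passed to [run_simulation()].
#' @return matrix of modulation SDs (rows = elevation or m, columns = n)
#'   with class `"rf_sweep"`; attributes `variant` and `kind`.
#' @export
sweep_rf_1d <- function(p, variant, n_list, elevation_rows = NULL,
                        stim = stimulus_spec(), grid = receptor_grid(),
                        ...) {
  if (is.null(elevation_rows))
    elevation_rows <- centred_indices(grid$n_elev, 1L)
  if (is.unsorted(n_list)) stop("n_list must be ascending")
  sub <- receptor_grid(phi = grid$phi,
                       elevation_of_row =
                         grid$elevation_of_row[elevation_rows])
  rfs <- list()
  for (i in seq_along(elevation_rows)) for (n in n_list) {
    rf <- rect_rf(1, n, sub)
    rf$w[] <- 0
    rf$w[i, if (n == sub$n_az) seq_len(sub$n_az) else {
      rec <- centred_receptor_cols(n, sub, 180)
      rec[-length(rec)]
    }] <- 1
    rfs[[length(rfs) + 1L]] <- rf
  }
  ref <- rect_rf(sub$n_elev, sub$n_az, sub)
  res <- run_simulation(p, variant, c(rfs, list(ref)), stim, grid = sub,
                        ...)
  N_ref <- normalize_response(res[[length(res)]])
  s <- matrix(NA_real_, length(elevation_rows), length(n_list),
              dimnames = list(
                elevation = format(sub$elevation_of_row, trim = TRUE),
                n = n_list))
  k <- 0L
  for (i in seq_along(elevation_rows)) for (j in seq_along(n_list)) {
    k <- k + 1L
    s[i, j] <- modulation_sd(normalize_response(res[[k]]), N_ref)
  }
  structure(s, class = c("rf_sweep", "matrix"), variant = variant,
            kind = "1d")
}

#' @rdname sweep_rf_1d
#' @export
sweep_rf_2d <- function(p, variant, m_list, n_list,
                        stim = stimulus_spec(), grid = receptor_grid(),
                        ...) {
  if (is.unsorted(m_list) || is.unsorted(n_list))
    stop("m_list and n_list must be ascending")
  m_max <- max(m_list)
  sub <- receptor_grid(phi = grid$phi,
                       elevation_of_row = grid$elevation_of_row[
                         centred_indices(grid$n_elev, m_max)])
  rfs <- list()
  for (m in m_list) for (n in n_list)
    rfs[[length(rfs) + 1L]] <- rect_rf(m, n, sub)
  ref <- rect_rf(sub$n_elev, sub$n_az, sub)
  res <- run_simulation(p, variant, c(rfs, list(ref)), stim, grid = sub,
                        ...)
  N_ref <- normalize_response(res[[length(res)]])
  s <- matrix(NA_real_, length(m_list), length(n_list),
              dimnames = list(m = m_list, n = n_list))
  k <- 0L
  for (i in seq_along(m_list)) for (j in seq_along(n_list)) {
    k <- k + 1L
    s[i, j] <- modulation_sd(normalize_response(res[[k]]), N_ref)
  }
  structure(s, class = c("rf_sweep", "matrix"), variant = variant,
            kind = "2d")
}

#' @export
print.rf_sweep <- function(x, ...) {
  cat("Modulation-SD sweep (", attr(x, "kind"), ", ",
      attr(x, "variant"), " variant)\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' @export
plot.rf_sweep <- function(x, ...) {
  m <- unclass(x)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(log10(m + 1e-12)),
                  xlab = "horizontal receptor count (index)",
                  ylab = "row (index)",
                  main = paste0("log10 modulation SD (",
                                attr(x, "variant"), ")"), ...)
  invisible(x)
}
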