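#' Normalize a response trace to its mean
#'
#' `N_t = (Z_t - Zbar) / Zbar` with `Zbar` the time mean over the retained
#' trace, giving dimensionless relative response units with mean exactly
#' zero. Undefined for traces whose mean is (numerically) zero;
#' preferred-direction motion yields positive means.
#'
#' @param trace an `"lptc_response"` or a numeric vector.
#' @return numeric vector `N_t`.
#' @export
normalize_response <- function(trace) {
  z <- if (inherits(trace, "lptc_response")) trace$Z else trace
  zbar <- mean(z)
  if (abs(zbar) < 1e-9)
    stop("mean response too close to zero; normalization undefined")
  (z - zbar) / zbar
}

#' Pattern-dependent modulation SD
#'
#' Root-mean-square deviation of a normalized response from the normalized
#' full-field reference response:
#' `s = sqrt(mean((N_mn - N_full)^2))` (population normalization, 1/T).
#' Vanishes identically when the receptive field comprises all receptive
#' channels.
#'
#' @param N_mn normalized trace of the receptive field under test.
#' @param N_full normalized trace of the full-field reference (same
#'   length).
#' @return non-negative scalar `s`.
#' @export
modulation_sd <- function(N_mn, N_full) {
  if (length(N_mn) != length(N_full))
    stop("traces must have equal length")
  sqrt(mean((N_mn - N_full)^2))
}

#' RMS contrast of a panorama
#'
#' Population standard deviation of the luminance over all pixels divided
#' by the global mean luminance.
#'
#' @param p a [panorama()] or numeric array.
#' @return non-negative scalar.
#' @export
rms_contrast <- function(p) {
  L <- if (inherits(p, "panorama")) p$luminance else p
  m <- mean(L)
  if (m <= 0) stop("RMS contrast undefined for a zero-mean image")
  sqrt(mean((L - m)^2)) / m
}

#' Percentage reduction between two modulation SDs
#'
#' `100 * (1 - s_test / s_ref)`: how much smaller the modulation SD of a
#' large receptive field is relative to a small reference field.
#'
#' @param s_ref reference SD (e.g. the two-receptor array); must be
#'   positive.
#' @param s_test SD under test (e.g. a 256-receptor array).
#' @return percentage.
#' @export
reduction_percentage <- function(s_ref, s_test) {
  if (any(s_ref <= 0)) stop("s_ref must be positive")
  100 * (1 - s_test / s_ref)
}

#' Collect sweep matrices into a long table with aggregate means
#'
#' Binds any number of [sweep_rf_1d()] / [sweep_rf_2d()] results (or plain
#' SD matrices) into a long-format data frame `(image, variant, m, n, s)`
#' and computes per-(variant, m, n) means over images. Row order is
#' deterministic (image, then variant, then m, then n).
#'
#' @param sweeps named list of sweep matrices; names identify the image
#'   (outer level) or `image` can be given per element via attributes.
#' @param image optional character vector of image ids, recycled along
#'   `sweeps`; defaults to the list names or the element index.
#' @return list with `table` (long data frame) and `means` (data frame of
#'   per-(variant, m, n) means over images).
#' @export
summarize_sweep <- function(sweeps, image = NULL) {
  if (inherits(sweeps, "rf_sweep")) sweeps <- list(sweeps)
  if (is.null(image)) {
    image <- names(sweeps)
    if (is.null(image)) image <- as.character(seq_along(sweeps))
  }
  image <- rep_len(image, length(sweeps))
  rows <- lapply(seq_along(sweeps), function(i) {
    m <- sweeps[[i]]
    dn <- dimnames(m)
    mm <- if (!is.null(dn) && identical(names(dn)[1], "m"))
      as.numeric(dn[[1]]) else rep(1, nrow(m))
    nn <- if (!is.null(dn)) as.numeric(dn[[2]]) else seq_len(ncol(m))
    data.frame(image = image[i],
               variant = attr(m, "variant") %||% NA_character_,
               m = rep(mm, times = ncol(m)),
               n = rep(nn, each = nrow(m)),
               s = as.vector(unclass(m)))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$image, tab$variant, tab$m, tab$n), , drop = FALSE]
  rownames(tab) <- NULL
  means <- stats::aggregate(s ~ variant + m + n, data = tab, FUN = mean)
  means <- means[order(means$variant, means$m, means$n), , drop = FALSE]
  rownames(means) <- NULL
  list(table = tab, means = means)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
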