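# Thermal-tune cantilever calibration: fit the resonance peak of a
# thermal-noise power spectrum with a damped simple-harmonic-oscillator
# (SHO) response, integrate the resonance power, and convert to a spring
# constant via the equipartition theorem k = kBT / <z^2>.

#' Thermal-noise power spectrum
#'
#' A cantilever thermal-noise spectrum: amplitude spectral density (nm^2/Hz)
#' on a strictly increasing positive frequency grid (Hz).
#'
#' @param frequency Frequencies in Hz, strictly increasing, > 0, length >= 16.
#' @param amplitude Spectral amplitudes in nm^2/Hz, >= 0, same length.
#' @param metadata Optional named list carried through file round trips.
#' @return An object of class `"power_spectrum"`.
#' @export
power_spectrum <- function(frequency, amplitude, metadata = list()) {
  stopifnot(is.numeric(frequency), is.numeric(amplitude))
  if (length(frequency) != length(amplitude)) {
    stop("frequency and amplitude must have equal length")
  }
  if (length(frequency) < 16L) {
    stop("spectrum must have at least 16 points")
  }
  if (any(frequency <= 0) || any(diff(frequency) <= 0)) {
    stop("frequencies must be positive and strictly increasing")
  }
  if (any(amplitude < 0)) stop("amplitudes must be non-negative")
  structure(
    list(frequency = frequency, amplitude = amplitude, metadata = metadata),
    class = "power_spectrum"
  )
}

#' Damped-SHO thermal response amplitude
#'
#' The model fitted to thermal-noise spectra:
#' \deqn{A(\nu) = A_0 + \frac{A_{DC}\,\nu_0^4}
#'   {(\nu_0^2-\nu^2)^2 + \nu_0^2\nu^2/Q^2},}
#' a white baseline plus a driven-oscillator resonance of centre frequency
#' `nu0`, zero-frequency amplitude `A_DC` and quality factor `Q`.
#'
#' @param frequency Frequencies in Hz.
#' @param baseline Baseline amplitude A_0 (nm^2/Hz).
#' @param dc_amplitude Zero-frequency resonance amplitude A_DC (nm^2/Hz).
#' @param resonance_freq Resonance centre frequency nu0 (Hz).
#' @param quality_factor Quality factor Q (> 0).
#' @return Model amplitudes in nm^2/Hz.
#' @export
sho_amplitude <- function(frequency, baseline, dc_amplitude,
                          resonance_freq, quality_factor) {
  nu2 <- frequency^2
  nu0_2 <- resonance_freq^2
  baseline + dc_amplitude * nu0_2^2 /
    ((nu0_2 - nu2)^2 + nu0_2 * nu2 / quality_factor^2)
}

#' Fit the SHO resonance of a thermal-noise spectrum
#'
#' Least-squares fit of [sho_amplitude()] to a thermal-noise spectrum.
#' Starting values, unless supplied, are taken from the data: `nu0` at the
#' spectrum argmax, `A_0` as the high-frequency median, `Q = 2`, `A_DC` from
#' the peak height. A spectrum with no discernible resonance (peak not
#' prominent above the baseline) is refused rather than silently fitted, and
#' a resonance at the edge of the frequency range is flagged.
#'
#' @param spectrum A [power_spectrum()].
#' @param init Optional named list overriding starting values (`baseline`,
#'   `dc_amplitude`, `resonance_freq`, `quality_factor`).
#' @return An object of class `"sho_fit"`: list with fields `baseline`,
#'   `dc_amplitude`, `resonance_freq`, `quality_factor`, `fit_residual`
#'   (sum of squared residuals) and logical `boundary_flag`.
#' @export
fit_resonance <- function(spectrum, init = NULL) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  nu <- spectrum$frequency
  A <- spectrum$amplitude

  i_max <- which.max(A)
  hi <- A[nu > 0.8 * max(nu)]
  base0 <- stats::median(if (length(hi) >= 4) hi else A)
  peak_height <- A[i_max] - base0
  if (!is.finite(peak_height) || peak_height <= 3 * max(base0, .Machine$double.eps)) {
    stop("no resonance peak detected above the baseline; cannot fit")
  }

  start <- list(
    baseline = max(base0, 1e-12 * A[i_max]),
    dc_amplitude = peak_height / (2^2),  # peak height ~ A_DC * Q^2 at resonance
    resonance_freq = nu[i_max],
    quality_factor = 2
  )
  if (!is.null(init)) {
    stopifnot(is.list(init))
    bad <- setdiff(names(init), names(start))
    if (length(bad)) stop("unknown init fields: ", paste(bad, collapse = ", "))
    start[names(init)] <- init
  }

  resid_fn <- function(par) {
    A - sho_amplitude(nu, par[1], par[2], par[3], par[4])
  }
  fit <- minpack.lm::nls.lm(
    par = unlist(start), fn = resid_fn,
    lower = c(0, 0, min(nu), 0.1),
    upper = c(Inf, Inf, max(nu), 1e4),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!fit$info %in% 1:4) {
    stop("resonance fit did not converge: ", fit$message)
  }
  cf <- as.list(stats::setNames(fit$par, names(start)))
  rng <- range(nu)
  span <- diff(rng)
  boundary <- cf[["resonance_freq"]] < rng[1] + 0.02 * span ||
    cf[["resonance_freq"]] > rng[2] - 0.02 * span
  if (boundary) {
    warning("fitted resonance frequency lies at the edge of the spectrum")
  }
  structure(
    list(
      baseline = cf[["baseline"]],
      dc_amplitude = cf[["dc_amplitude"]],
      resonance_freq = cf[["resonance_freq"]],
      quality_factor = cf[["quality_factor"]],
      fit_residual = fit$deviance,
      boundary_flag = boundary
    ),
    class = "sho_fit"
  )
}

#' @export
print.sho_fit <- function(x, ...) {
  cat(sprintf(
    "SHO fit: nu0 = %.4g Hz, Q = %.4g, A_DC = %.4g nm^2/Hz, A0 = %.4g (SSR %.3g)\n",
    x$resonance_freq, x$quality_factor, x$dc_amplitude, x$baseline,
    x$fit_residual))
  invisible(x)
}

#' Power under the fitted resonance peak
#'
#' Integral of the resonance term of a fitted SHO response (baseline
#' excluded) over all frequencies. The integral has the closed form
#' \eqn{P = (\pi/2) A_{DC} \nu_0 Q}; by default this analytic value is
#' returned, with adaptive quadrature (relative tolerance 1e-6) available as
#' a cross-check.
#'
#' @param fit An [fit_resonance()] result (class `"sho_fit"`), or any list
#'   with fields `dc_amplitude`, `resonance_freq`, `quality_factor`.
#' @param method `"analytic"` (default) or `"quadrature"`.
#' @return Peak power P in nm^2 (equals the mean-square displacement).
#' @export
peak_power <- function(fit, method = c("analytic", "quadrature")) {
  method <- match.arg(method)
  A_DC <- fit$dc_amplitude
  nu0 <- fit$resonance_freq
  Q <- fit$quality_factor
  stopifnot(A_DC >= 0, nu0 > 0, Q > 0)
  if (A_DC == 0) return(0)
  if (method == "analytic") {
    return((pi / 2) * A_DC * nu0 * Q)
  }
  shape <- function(v) {
    sho_amplitude(v, baseline = 0, dc_amplitude = A_DC,
                  resonance_freq = nu0, quality_factor = Q)
  }
  core <- stats::integrate(shape, 0, 3 * nu0, rel.tol = 1e-6,
                           subdivisions = 500L)$value
  tail <- stats::integrate(shape, 3 * nu0, Inf, rel.tol = 1e-6,
                           subdivisions = 500L)$value
  core + tail
}

#' Spring constant from equipartition
#'
#' Cantilever spring constant from the thermal-noise peak power (the mean
#' square deflection): `k = kBT / P`, reported in N/m.
#'
#' @param peak_power Peak power P in nm^2 (> 0).
#' @param temperature Absolute temperature in K.
#' @return Spring constant in N/m.
#' @examples
#' spring_constant(0.0274)   # ~ 0.15 N/m
#' @export
spring_constant <- function(peak_power, temperature = 298) {
  stopifnot(is.numeric(peak_power))
  if (any(peak_power <= 0)) stop("peak_power must be positive")
  k_pN_nm <- thermal_energy(temperature) / peak_power
  convert_spring_constant(k_pN_nm, "pN/nm", "N/m")
}

#' Calibration result container
#'
#' @param spring_constant Spring constant in N/m (> 0).
#' @param peak_power Peak power in nm^2 (> 0).
#' @param temperature Absolute temperature in K.
#' @return An object of class `"calibration_result"`.
#' @export
calibration_result <- function(spring_constant, peak_power,
                               temperature = 298) {
  stopifnot(spring_constant > 0, peak_power > 0, temperature > 0)
  structure(
    list(spring_constant = spring_constant, peak_power = peak_power,
         temperature = temperature),
    class = "calibration_result"
  )
}

#' Full thermal-tune calibration of one spectrum
#'
#' Convenience pipeline: [fit_resonance()] then [peak_power()] then
#' [spring_constant()].
#'
#' @param spectrum A [power_spectrum()].
#' @param temperature Absolute temperature in K.
#' @param init Optional starting values passed to [fit_resonance()].
#' @return A [calibration_result()] with the SHO fit attached as
#'   attribute `"fit"`.
#' @export
calibrate_spectrum <- function(spectrum, temperature = 298, init = NULL) {
  fit <- fit_resonance(spectrum, init = init)
  P <- peak_power(fit)
  res <- calibration_result(spring_constant(P, temperature), P, temperature)
  attr(res, "fit") <- fit
  res
}

#' Average repeated calibrations
#'
#' Arithmetic mean of the spring constants of repeated thermal-tune
#' calibrations, with the relative spread (sample standard deviation over
#' mean). A single calibration yields an `NA` spread.
#'
#' @param results A list of [calibration_result()] objects (or a numeric
#'   vector of spring constants in N/m).
#' @return A list: `spring_constant` (mean, N/m), `relative_spread`
#'   (sd/mean, `NA` for a single entry), `n`.
#' @examples
#' aggregate_calibrations(c(0.12, 0.15, 0.18))
#' @export
aggregate_calibrations <- function(results) {
  if (is.numeric(results)) {
    k <- results
  } else {
    stopifnot(is.list(results), length(results) >= 1L)
    k <- vapply(results, function(r) {
      stopifnot(inherits(r, "calibration_result"))
      r$spring_constant
    }, numeric(1))
  }
  if (length(k) < 1L) stop("at least one calibration result is required")
  m <- mean(k)
  spread <- if (length(k) >= 2L) stats::sd(k) / m else NA_real_
  list(spring_constant = m, relative_spread = spread, n = length(k))
}

#' Simulate a thermal-noise spectrum
#'
#' Fixture generator for calibration: evaluates the SHO response on a
#' frequency grid and applies multiplicative Gaussian noise. Either explicit
#' SHO parameters or a target spring constant may be given; in the latter
#' case `A_DC` is chosen so that the resonance power equals `kBT / k`.
#'
#' @param fit A list of SHO parameters (`baseline`, `dc_amplitude`,
#'   `resonance_freq`, `quality_factor`), e.g. an [fit_resonance()] result.
#'   Ignored if `target_k` is given (except `resonance_freq` and
#'   `quality_factor`, which are reused when present).
#' @param temperature Absolute temperature in K.
#' @param noise_level Multiplicative noise standard deviation (0 = exact
#'   model evaluation).
#' @param seed Integer seed; required when `noise_level > 0`.
#' @param target_k Optional target spring constant in N/m.
#' @param frequency Frequency grid in Hz; default 512 points spanning
#'   0.05-5 times the resonance frequency.
#' @return A [power_spectrum()].
#' @export
simulate_thermal_spectrum <- function(fit = NULL, temperature = 298,
                                      noise_level = 0, seed = NULL,
                                      target_k = NULL, frequency = NULL) {
  nu0 <- if (!is.null(fit$resonance_freq)) fit$resonance_freq else 3000
  Q <- if (!is.null(fit$quality_factor)) fit$quality_factor else 2
  A0 <- if (!is.null(fit$baseline)) fit$baseline else 0
  if (!is.null(target_k)) {
    stopifnot(target_k > 0)
    P <- thermal_energy(temperature) /
      convert_spring_constant(target_k, "N/m", "pN/nm")
    A_DC <- P / ((pi / 2) * nu0 * Q)
    if (is.null(fit$baseline)) A0 <- 0.05 * A_DC
  } else {
    stopifnot(!is.null(fit$dc_amplitude))
    A_DC <- fit$dc_amplitude
  }
  if (is.null(frequency)) {
    frequency <- seq(0.05 * nu0, 5 * nu0, length.out = 512L)
  }
  amp <- sho_amplitude(frequency, A0, A_DC, nu0, Q)
  if (noise_level > 0) {
    if (is.null(seed)) stop("seed is required when noise_level > 0")
    set.seed(seed)
    amp <- pmax(amp * (1 + noise_level * stats::rnorm(length(amp))), 0)
  }
  power_spectrum(frequency, amp,
                 metadata = list(temperature_K = temperature))
}
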