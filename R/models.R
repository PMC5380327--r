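# Closed-form physical models shared by all pipeline stages:
# worm-like-chain elasticity, Bell unfolding kinetics, the Evans
# most-probable rupture force under constant loading, contour-length
# accounting, and free-calcium bookkeeping with EDTA.

#' Worm-like-chain parameters
#'
#' Parameter container for the interpolation-formula worm-like chain (WLC):
#' a persistence length `L_p` (bending stiffness scale), a contour length
#' `L_c` (fully stretched backbone length) and the temperature at which the
#' thermal energy is evaluated.
#'
#' @param persistence_length Persistence length L_p in nm (> 0).
#' @param contour_length Contour length L_c in nm (> 0).
#' @param temperature Absolute temperature in K (> 0).
#' @return An object of class `"wlc_params"`.
#' @examples
#' wlc_params(persistence_length = 0.3, contour_length = 38)
#' @export
wlc_params <- function(persistence_length, contour_length, temperature = 298) {
  stopifnot(
    is.numeric(persistence_length), length(persistence_length) == 1L,
    is.numeric(contour_length), length(contour_length) == 1L,
    persistence_length > 0, contour_length > 0, temperature > 0
  )
  structure(
    list(
      persistence_length = persistence_length,
      contour_length = contour_length,
      temperature = temperature
    ),
    class = "wlc_params"
  )
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("WLC: L_p = %g nm, L_c = %g nm, T = %g K\n",
              x$persistence_length, x$contour_length, x$temperature))
  invisible(x)
}

#' Bell-model kinetic parameters
#'
#' Parameters of the Bell model for force-activated unfolding: the unfolding
#' rate at zero force `k_u0` and the distance `x_u` from the folded state to
#' the transition state along the pulling coordinate. All prefactors
#' (attempt frequency, transmission coefficient, activation energy) are
#' absorbed into `k_u0`.
#'
#' @param k_u0 Unfolding rate constant at zero force, in 1/s (> 0).
#' @param x_u Distance to the transition state, in nm (> 0).
#' @param temperature Absolute temperature in K (> 0).
#' @return An object of class `"bell_params"`.
#' @examples
#' bell_params(k_u0 = 0.003, x_u = 0.2)
#' @export
bell_params <- function(k_u0, x_u, temperature = 298) {
  stopifnot(
    is.numeric(k_u0), length(k_u0) == 1L, k_u0 > 0,
    is.numeric(x_u), length(x_u) == 1L, x_u > 0,
    temperature > 0
  )
  structure(
    list(k_u0 = k_u0, x_u = x_u, temperature = temperature),
    class = "bell_params"
  )
}

#' @export
print.bell_params <- function(x, ...) {
  cat(sprintf("Bell kinetics: k_u0 = %g 1/s, x_u = %g nm, T = %g K\n",
              x$k_u0, x$x_u, x$temperature))
  invisible(x)
}

#' Worm-like-chain force at a given extension
#'
#' Entropic restoring force of a worm-like chain at extension `x`, using the
#' standard interpolation formula
#' \deqn{F(x) = \frac{k_B T}{L_p}\left[\frac{1}{4}\left(1 - x/L_c\right)^{-2}
#'   - \frac{1}{4} + x/L_c\right].}
#' The force is zero at zero extension, strictly increasing, and diverges as
#' the extension approaches the contour length.
#'
#' @param extension Extension(s) x in nm; must satisfy 0 <= x < L_c.
#' @param params A [wlc_params()] object.
#' @return Force(s) in pN.
#' @examples
#' p <- wlc_params(0.3, 38)
#' wlc_force(30, p)             # ~ 84.8 pN
#' wlc_force(p$contour_length / 2, p)  # 1.25 * kBT / L_p
#' @export
wlc_force <- function(extension, params) {
  stopifnot(inherits(params, "wlc_params"), is.numeric(extension))
  Lc <- params$contour_length
  if (any(!is.finite(extension)) || any(extension < 0) || any(extension >= Lc)) {
    stop("extension must satisfy 0 <= extension < contour_length")
  }
  kT <- thermal_energy(params$temperature)
  t <- extension / Lc
  (kT / params$persistence_length) * (0.25 * (1 - t)^-2 - 0.25 + t)
}

#' Worm-like-chain extension at a given force
#'
#' Numerical inverse of [wlc_force()]: the extension at which the WLC exerts
#' the requested force. Solved by bracketed root finding on the fractional
#' extension; the round-trip error `|wlc_force(wlc_extension(F)) - F|` is
#' below 1e-6 pN over the working force range.
#'
#' @param force Force(s) in pN; must be >= 0.
#' @param params A [wlc_params()] object.
#' @return Extension(s) in nm, in `[0, L_c)`.
#' @examples
#' p <- wlc_params(0.3, 38)
#' wlc_extension(wlc_force(30, p), p)  # 30
#' @export
wlc_extension <- function(force, params) {
  stopifnot(inherits(params, "wlc_params"), is.numeric(force))
  if (any(!is.finite(force)) || any(force < 0)) {
    stop("force must be non-negative and finite")
  }
  Lc <- params$contour_length
  a <- thermal_energy(params$temperature) / params$persistence_length
  vapply(force, function(f) {
    if (f == 0) return(0)
    g <- function(t) 0.25 * (1 - t)^-2 - 0.25 + t - f / a
    # g is strictly increasing on [0, 1); bracket the root tightly.
    upper <- 1 - 1e-12
    root <- stats::uniroot(g, c(0, upper), tol = 1e-14)$root
    root * Lc
  }, numeric(1))
}

#' Bell-model unfolding rate at a given force
#'
#' Force-dependent unfolding rate
#' \deqn{k_u(F) = k_{u}^{0} \exp(F x_u / k_B T),}
#' i.e. the zero-force rate accelerated exponentially by the mechanical work
#' over the transition-state distance.
#'
#' @param force Force(s) in pN; must be >= 0.
#' @param params A [bell_params()] object.
#' @return Rate(s) in 1/s.
#' @examples
#' b <- bell_params(0.003, 0.2)
#' bell_rate(0, b)     # k_u0
#' bell_rate(348, b)   # ~ 6.7e4 1/s
#' @export
bell_rate <- function(force, params) {
  stopifnot(inherits(params, "bell_params"), is.numeric(force))
  if (any(!is.finite(force)) || any(force < 0)) {
    stop("force must be non-negative and finite")
  }
  kT <- thermal_energy(params$temperature)
  params$k_u0 * exp(force * params$x_u / kT)
}

#' Most probable rupture force under constant loading (Evans model)
#'
#' For a Bell-model bond loaded at constant rate r (pN/s), the most probable
#' rupture force is
#' \deqn{F^*(r) = \frac{k_B T}{x_u}\,
#'   \ln\!\left(\frac{r\,x_u}{k_B T\,k_u^0}\right),}
#' linear in `ln r` with slope `k_B T / x_u`. When the log argument is at or
#' below 1 the model predicts no positive most-probable force; the function
#' then returns 0 and flags the value as out of regime via the `"in_regime"`
#' attribute.
#'
#' @param loading_rate Loading rate(s) r in pN/s; must be > 0.
#' @param params A [bell_params()] object.
#' @return Force(s) in pN with a logical attribute `"in_regime"` of the same
#'   length (FALSE where the log argument was <= 1 and 0 was returned).
#' @examples
#' b <- bell_params(0.003, 0.2)
#' evans_force(1.5e5, b)   # ~ 302 pN
#' @export
evans_force <- function(loading_rate, params) {
  stopifnot(inherits(params, "bell_params"), is.numeric(loading_rate))
  if (any(!is.finite(loading_rate)) || any(loading_rate <= 0)) {
    stop("loading_rate must be positive and finite")
  }
  kT <- thermal_energy(params$temperature)
  arg <- loading_rate * params$x_u / (kT * params$k_u0)
  in_regime <- arg > 1
  f <- ifelse(in_regime, (kT / params$x_u) * log(pmax(arg, 1)), 0)
  attr(f, "in_regime") <- in_regime
  f
}

#' Rupture-force distribution under constant loading
#'
#' Analytic distribution of the rupture force of a Bell-model bond loaded at
#' constant rate r. The survival probability is
#' \deqn{S(F) = \exp\!\left[-\frac{k_u^0 k_B T}{x_u r}
#'   \left(e^{F x_u / k_B T} - 1\right)\right],}
#' the density is \eqn{f(F) = k_u(F) S(F) / r}, and the mode coincides with
#' [evans_force()] whenever that force is in regime. The quantile function is
#' analytic, which makes exact inverse-CDF sampling possible (see
#' [simulate_constant_loading()]).
#'
#' @param loading_rate Loading rate r in pN/s (scalar, > 0).
#' @param params A [bell_params()] object.
#' @return An object of class `"rupture_dist"`: a list with vectorised
#'   functions `pdf(F)`, `cdf(F)`, `survival(F)`, `quantile(p)`, plus the
#'   scalar `mode` and logical `in_regime`.
#' @examples
#' d <- rupture_force_distribution(1.5e5, bell_params(0.003, 0.2))
#' d$survival(0)   # 1
#' d$mode          # equals evans_force at this rate
#' @export
rupture_force_distribution <- function(loading_rate, params) {
  stopifnot(inherits(params, "bell_params"),
            is.numeric(loading_rate), length(loading_rate) == 1L,
            is.finite(loading_rate), loading_rate > 0)
  kT <- thermal_energy(params$temperature)
  x_u <- params$x_u
  k0 <- params$k_u0
  beta <- x_u / kT                 # 1/pN
  A <- k0 / (beta * loading_rate)  # dimensionless hazard scale

  survival <- function(force) {
    stopifnot(all(force >= 0))
    exp(-A * (exp(beta * force) - 1))
  }
  cdf <- function(force) 1 - survival(force)
  pdf <- function(force) {
    stopifnot(all(force >= 0))
    (k0 * exp(beta * force) / loading_rate) * survival(force)
  }
  quantile <- function(p) {
    stopifnot(all(p >= 0 & p < 1))
    # S(F) = 1 - p  =>  F = (1/beta) log(1 - log(1 - p)/A)
    log1p(-log1p(-p) / A) / beta
  }
  mode_force <- evans_force(loading_rate, params)
  structure(
    list(
      pdf = pdf, cdf = cdf, survival = survival, quantile = quantile,
      mode = as.numeric(mode_force),
      in_regime = attr(mode_force, "in_regime"),
      loading_rate = loading_rate, params = params
    ),
    class = "rupture_dist"
  )
}

#' Contour-length increase per amino acid
#'
#' The contour length gained per residue when one folded monomer unfolds:
#' the total unfolded monomer length is the contour-length increment
#' `delta_Lc` observed between consecutive unfolding peaks plus the folded
#' N-to-C terminal distance `d_NC`, divided by the residue count,
#' \deqn{L_{aa} = (\Delta L_c + d_{N;C}) / N_{aa}.}
#' Typical values for fully stretched polypeptides are 0.36-0.40 nm/aa.
#'
#' @param delta_Lc Contour-length increase per unfolding event, nm (>= 0).
#' @param d_NC Folded N- to C-terminus distance, nm (>= 0).
#' @param n_aa Number of residues in the monomer (integer >= 1).
#' @param digits Optional number of decimals for reporting; `NULL` (default)
#'   returns full precision.
#' @return Contour length per amino acid in nm/aa.
#' @examples
#' contour_per_aa(33.2, 4.8, 104, digits = 2)   # 0.37
#' contour_per_aa(33.6, 3.38, 97, digits = 2)   # 0.38
#' @export
contour_per_aa <- function(delta_Lc, d_NC, n_aa, digits = NULL) {
  stopifnot(is.numeric(delta_Lc), is.numeric(d_NC), is.numeric(n_aa))
  if (any(delta_Lc < 0) || any(d_NC < 0)) {
    stop("delta_Lc and d_NC must be non-negative")
  }
  if (any(n_aa < 1) || any(n_aa != round(n_aa))) {
    stop("n_aa must be a positive integer residue count")
  }
  out <- (delta_Lc + d_NC) / n_aa
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Free calcium after EDTA chelation
#'
#' Free Ca2+ concentration of a buffer containing EDTA, under the
#' strong-binding 1:1 approximation (EDTA binds Ca2+ essentially
#' stoichiometrically at the working pH): free = max(total - EDTA, 0).
#'
#' @param total_ca Total calcium concentration, mM (>= 0).
#' @param edta EDTA concentration, mM (>= 0).
#' @return Free calcium concentration in mM.
#' @examples
#' free_calcium(0.13, 0.1)   # 0.03 mM = 30 uM
#' free_calcium(10.1, 0.1)   # 10 mM
#' @export
free_calcium <- function(total_ca, edta) {
  stopifnot(is.numeric(total_ca), is.numeric(edta))
  if (any(total_ca < 0) || any(edta < 0)) {
    stop("concentrations must be non-negative")
  }
  pmax(total_ca - edta, 0)
}
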