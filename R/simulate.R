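# Monte Carlo simulation of constant-speed AFM pulling on tandem
# polyproteins. The tether is modelled quasi-statically as a worm-like
# chain in series with a Hookean cantilever; at each time step the piezo
# position advances, the force balance is solved, and each folded domain
# (and the tip-protein attachment) may rupture with a Bell-model hazard.

#' Domain specification for the pulling simulator
#'
#' One protein domain of a tandem construct. `unfolded_contour` is the full
#' contour length of the unfolded monomer (the observable contour-length
#' increment per unfolding is `unfolded_contour - folded_NC`).
#'
#' @param name Domain label (e.g. "RII", "GFP").
#' @param n_residues Residue count (>= 1).
#' @param folded_NC Folded N-to-C terminal distance in nm (>= 0); the length
#'   the folded domain contributes to the tether.
#' @param unfolded_contour Contour length of the fully unfolded monomer in
#'   nm (> folded_NC).
#' @param kinetics A [bell_params()] object for the domain's unfolding.
#' @return An object of class `"domain_spec"`.
#' @export
domain_spec <- function(name, n_residues, folded_NC, unfolded_contour,
                        kinetics) {
  stopifnot(
    is.character(name), length(name) == 1L,
    n_residues >= 1, n_residues == round(n_residues),
    folded_NC >= 0, unfolded_contour > 0,
    unfolded_contour > folded_NC,
    inherits(kinetics, "bell_params")
  )
  structure(
    list(name = name, n_residues = n_residues, folded_NC = folded_NC,
         unfolded_contour = unfolded_contour, kinetics = kinetics),
    class = "domain_spec"
  )
}

#' Built-in domain presets
#'
#' Domain parameter sets used throughout the package. Geometry (residue
#' counts, folded N-to-C distances, unfolded contour lengths) follows the
#' crystal-structure / homology-model values for the adhesin RII repeats and
#' published fingerprints for GFP and titin I27. Bell kinetics for `"RII"`
#' are the loading-rate-fit estimates (x_u = 0.2 nm, k_u0 = 0.003 1/s); the
#' other presets' kinetics are calibrated so that the mean simulated
#' unfolding force at a 1 um/s pulling speed (0.15 N/m cantilever) matches
#' the reported mean unfolding forces (~306 pN MhLap RII, ~88 pN GFP,
#' ~218 pN I27) -- they are package presets, not measured kinetic constants.
#'
#' @param name One of `"RII"`, `"MhLapRII"`, `"GFP"`, `"I27"`.
#' @param temperature Absolute temperature in K for the kinetics.
#' @return A [domain_spec()].
#' @examples
#' domain_preset("RII")
#' @export
domain_preset <- function(name = c("RII", "MhLapRII", "GFP", "I27"),
                          temperature = 298) {
  name <- match.arg(name)
  switch(name,
    RII = domain_spec("RII", 104, 4.8, 38.0,
                      bell_params(0.003, 0.2, temperature)),
    MhLapRII = domain_spec("MhLapRII", 97, 3.38, 36.98,
                           bell_params(6.3e-4, 0.22, temperature)),
    GFP = domain_spec("GFP", 239, 3.0, 77.4,
                      bell_params(0.059, 0.6, temperature)),
    I27 = domain_spec("I27", 89, 4.3, 31.6,
                      bell_params(1.4e-3, 0.3, temperature))
  )
}

#' Tandem construct specification
#'
#' An ordered chain of domains (N- to C-terminal) plus an inert linker
#' contour and the persistence length used for the chain's worm-like-chain
#' elasticity.
#'
#' @param domains List of [domain_spec()] objects, length >= 1.
#' @param linker_contour Inert linker contour length in nm (>= 0).
#' @param persistence_length Chain persistence length in nm (> 0).
#' @return An object of class `"construct_spec"`.
#' @export
construct_spec <- function(domains, linker_contour = 0,
                           persistence_length = 0.3) {
  stopifnot(is.list(domains), length(domains) >= 1L,
            all(vapply(domains, inherits, logical(1), "domain_spec")),
            linker_contour >= 0, persistence_length > 0)
  structure(
    list(domains = domains, linker_contour = linker_contour,
         persistence_length = persistence_length),
    class = "construct_spec"
  )
}

#' Built-in construct presets
#'
#' Octameric polyprotein constructs mirroring the experimental designs:
#' `"RII8"` (eight identical RII repeats), `"RII8-GFP"` (two RII
#' tetra-tandemers flanking one GFP), `"MhLapRII8"` (eight MhLap RII repeats
#' with a fixed spread of log zero-force rates emulating their imperfect
#' sequence identity) and `"I278"` (eight titin I27 repeats).
#'
#' @param name One of `"RII8"`, `"RII8-GFP"`, `"MhLapRII8"`, `"I278"`.
#' @param temperature Absolute temperature in K.
#' @param mhlap_ku0_spread Standard deviation of log k_u0 across the MhLap
#'   repeats (heterogeneity of the non-identical repeats); 0 gives identical
#'   repeats.
#' @return A [construct_spec()].
#' @examples
#' construct_preset("RII8")
#' @export
construct_preset <- function(name = c("RII8", "RII8-GFP", "MhLapRII8", "I278"),
                             temperature = 298, mhlap_ku0_spread = 1.9) {
  name <- match.arg(name)
  rep_dom <- function(d, n) replicate(n, d, simplify = FALSE)
  switch(name,
    "RII8" = construct_spec(rep_dom(domain_preset("RII", temperature), 8)),
    "RII8-GFP" = {
      rii <- domain_preset("RII", temperature)
      gfp <- domain_preset("GFP", temperature)
      construct_spec(c(rep_dom(rii, 4), list(gfp), rep_dom(rii, 4)))
    },
    "MhLapRII8" = {
      base <- domain_preset("MhLapRII", temperature)
      # fixed, symmetric spread of log k_u0 -> mean force preserved
      d <- seq(-1.75, 1.75, length.out = 8)
      d <- d / stats::sd(d) * mhlap_ku0_spread
      doms <- lapply(seq_len(8), function(i) {
        k <- base$kinetics
        domain_spec(base$name, base$n_residues, base$folded_NC,
                    base$unfolded_contour,
                    bell_params(k$k_u0 * exp(d[i]), k$x_u, k$temperature))
      })
      construct_spec(doms)
    },
    "I278" = construct_spec(rep_dom(domain_preset("I27", temperature), 8))
  )
}

#' Pulling protocol
#'
#' Acquisition parameters of one constant-speed pulling ramp.
#'
#' @param speed Pulling speed v in nm/s (> 0).
#' @param cantilever_k Cantilever spring constant (> 0), in the unit given
#'   by `k_unit`.
#' @param k_unit `"N/m"` (default) or `"pN/nm"`.
#' @param ramp_length Ramp length in nm (> 0); default 1000 nm (1 um).
#' @param sample_interval Sampling interval in s, or `NULL` (default) for a
#'   speed-matched interval giving 0.5 nm of piezo travel per sample.
#' @param temperature Absolute temperature in K.
#' @return An object of class `"pulling_protocol"`; the spring constant is
#'   carried internally in pN/nm (`cantilever_k`), with `cantilever_k_N_m`
#'   kept for reporting.
#' @export
pulling_protocol <- function(speed, cantilever_k = 0.15, k_unit = "N/m",
                             ramp_length = 1000, sample_interval = NULL,
                             temperature = 298) {
  stopifnot(speed > 0, cantilever_k > 0, ramp_length > 0, temperature > 0)
  k_pN_nm <- convert_spring_constant(cantilever_k, match.arg(k_unit,
    c("N/m", "pN/nm")), "pN/nm")
  if (is.null(sample_interval)) sample_interval <- 0.5 / speed
  stopifnot(sample_interval > 0)
  structure(
    list(speed = speed, cantilever_k = k_pN_nm,
         cantilever_k_N_m = convert_spring_constant(k_pN_nm, "pN/nm", "N/m"),
         ramp_length = ramp_length, sample_interval = sample_interval,
         temperature = temperature),
    class = "pulling_protocol"
  )
}

#' Measurement noise and artifact model
#'
#' Instrumental and experimental nuisance processes applied to simulated
#' curves: Gaussian force noise, linear baseline drift, a nonspecific
#' tip-substrate adhesion bump at small extensions, Bell kinetics of the
#' tip-protein attachment (whose rupture ends the trace), the per-ramp
#' molecule pickup probability, and the probability that the GFP domain is
#' misfolded from the start (contributing unfolded contour, no peak).
#'
#' @param force_noise_sd Gaussian force noise sd in pN (>= 0).
#' @param baseline_drift Linear baseline drift in pN/nm (may be 0).
#' @param adhesion_amplitude Mean adhesion amplitude at zero extension in pN
#'   (>= 0).
#' @param adhesion_range Exponential decay length of the adhesion bump in nm
#'   (> 0).
#' @param tether_kinetics [bell_params()] of the tip-protein attachment.
#' @param pickup_probability Per-ramp probability of picking up a molecule,
#'   in `[0, 1]`.
#' @param gfp_misfold_probability Probability that a GFP domain is misfolded
#'   at the start of a pull, in `[0, 1]`.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(force_noise_sd = 10, baseline_drift = 0,
                        adhesion_amplitude = 150, adhesion_range = 15,
                        tether_kinetics = bell_params(1e-5, 0.15),
                        pickup_probability = 0.03,
                        gfp_misfold_probability = 0.5) {
  stopifnot(force_noise_sd >= 0, adhesion_amplitude >= 0, adhesion_range > 0,
            inherits(tether_kinetics, "bell_params"),
            pickup_probability >= 0, pickup_probability <= 1,
            gfp_misfold_probability >= 0, gfp_misfold_probability <= 1)
  structure(
    list(force_noise_sd = force_noise_sd, baseline_drift = baseline_drift,
         adhesion_amplitude = adhesion_amplitude,
         adhesion_range = adhesion_range,
         tether_kinetics = tether_kinetics,
         pickup_probability = pickup_probability,
         gfp_misfold_probability = gfp_misfold_probability),
    class = "noise_model"
  )
}

# Solve the series force balance z = x + F(x)/k_c for the protein extension
# x, where F is the WLC force at total contour Lc. Newton iteration with a
# bisection fallback; returns the extension in [0, Lc).
solve_force_balance <- function(z, Lc, a, k_c, x0 = NULL) {
  if (z <= 0) return(0)
  upper <- Lc * (1 - 1e-12)
  wlc <- function(x) {
    t <- x / Lc
    a * (0.25 * (1 - t)^-2 - 0.25 + t)
  }
  h <- function(x) x + wlc(x) / k_c - z
  x <- if (is.null(x0)) min(z, 0.9 * Lc) else min(max(x0, 0), upper)
  ok <- FALSE
  for (i in 1:60) {
    t <- x / Lc
    dF <- a * (0.5 * (1 - t)^-3 + 1) / Lc
    step <- h(x) / (1 + dF / k_c)
    x_new <- x - step
    if (x_new <= 0) x_new <- x / 2
    if (x_new >= upper) x_new <- (x + upper) / 2
    if (abs(x_new - x) < 1e-11) {
      x <- x_new
      ok <- TRUE
      break
    }
    x <- x_new
  }
  if (!ok || abs(h(x)) > 1e-6) {
    x <- tryCatch(
      stats::uniroot(h, c(0, upper), tol = 1e-12)$root,
      error = function(e) stop("force-balance root finding failed at z = ",
                               signif(z, 6), " nm: ", conditionMessage(e))
    )
  }
  x
}

empty_event_log <- function() {
  data.frame(time_s = numeric(0), piezo_nm = numeric(0),
             extension_nm = numeric(0), force_pN = numeric(0),
             domain = character(0), type = character(0),
             stringsAsFactors = FALSE)
}

#' Simulate one constant-speed pulling ramp
#'
#' Quasi-static Monte Carlo pull of a tandem construct: at each time step
#' the piezo advances by `v * dt`, the series force balance
#' `z = x + F/k_c` (worm-like-chain tether in series with a Hookean
#' cantilever) is solved for the force, and each still-folded domain and the
#' tip-protein attachment may rupture with Bell-model hazard
#' `1 - exp(-k_u(F) dt)`. An unfolding event adds the domain's unfolded
#' contour (minus its folded N-to-C spacer) to the tether; attachment
#' rupture ("detach") drops the force to the baseline for the remainder of
#' the ramp. When the total per-step hazard exceeds 0.1 the step is
#' subdivided so that at most one event occurs per substep. Gaussian force
#' noise, baseline drift and a nonspecific adhesion bump are applied to the
#' recorded trace only (ground-truth event forces are noise-free).
#'
#' @param construct A [construct_spec()].
#' @param protocol A [pulling_protocol()].
#' @param noise A [noise_model()].
#' @param seed Integer seed, or `NULL` to continue the current RNG stream
#'   (used by [simulate_experiment()]).
#' @param curve_id Identifier stored in the curve metadata.
#' @return A list with `curve` (a [force_curve()], extension = tip-sample
#'   separation in nm, force in pN) and `events` (data frame: `time_s`,
#'   `piezo_nm`, `extension_nm`, `force_pN`, `domain`, `type` in
#'   `{"unfold", "detach"}`, time-ordered, at most one detach and always
#'   last).
#' @examples
#' sim <- simulate_pull(construct_preset("RII8"),
#'                      pulling_protocol(speed = 1000), seed = 1)
#' nrow(sim$events)
#' @export
simulate_pull <- function(construct, protocol, noise = noise_model(),
                          seed = NULL, curve_id = "curve") {
  stopifnot(inherits(construct, "construct_spec"),
            inherits(protocol, "pulling_protocol"),
            inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)

  kT <- thermal_energy(protocol$temperature)
  a <- kT / construct$persistence_length
  k_c <- protocol$cantilever_k
  v <- protocol$speed
  dt <- protocol$sample_interval
  n_steps <- ceiling(protocol$ramp_length / (v * dt))

  doms <- construct$domains
  n_dom <- length(doms)
  folded <- rep(TRUE, n_dom)
  d_NC <- vapply(doms, `[[`, numeric(1), "folded_NC")
  L_unf <- vapply(doms, `[[`, numeric(1), "unfolded_contour")
  names_dom <- vapply(doms, `[[`, character(1), "name")
  beta_dom <- vapply(doms, function(d) d$kinetics$x_u /
                       thermal_energy(d$kinetics$temperature), numeric(1))
  k0_dom <- vapply(doms, function(d) d$kinetics$k_u0, numeric(1))
  tk <- noise$tether_kinetics
  beta_t <- tk$x_u / thermal_energy(tk$temperature)
  k0_t <- tk$k_u0

  # GFP misfolding: the domain starts unfolded and produces no event
  is_gfp <- names_dom == "GFP"
  if (any(is_gfp) && noise$gfp_misfold_probability > 0) {
    mis <- is_gfp & (stats::runif(n_dom) < noise$gfp_misfold_probability)
    folded[mis] <- FALSE
  }

  Lc <- construct$linker_contour + sum(ifelse(folded, d_NC, L_unf))
  rates_at <- function(F) {
    r <- numeric(n_dom)
    r[folded] <- k0_dom[folded] * exp(F * beta_dom[folded])
    r
  }

  ext <- numeric(n_steps)
  frc <- numeric(n_steps)
  ev_t <- ev_z <- ev_x <- ev_F <- numeric(0)
  ev_d <- ev_type <- character(0)
  detached <- FALSE
  x_prev <- 0

  for (i in seq_len(n_steps)) {
    t_i <- i * dt
    z <- v * t_i
    if (detached) {
      ext[i] <- z
      frc[i] <- 0
      next
    }
    x <- solve_force_balance(z, Lc, a, k_c, x0 = x_prev + v * dt)
    F <- k_c * (z - x)

    remaining <- dt
    while (remaining > 0 && !detached) {
      r_dom <- rates_at(F)
      r_tet <- k0_t * exp(F * beta_t)
      R <- sum(r_dom) + r_tet
      if (!is.finite(R) || R <= 0) {
        if (is.finite(R)) break          # nothing can rupture
        dt_sub <- remaining
        p <- 1
      } else {
        dt_sub <- if (R * remaining > 0.1) min(0.05 / R, remaining) else remaining
        p <- 1 - exp(-R * dt_sub)
      }
      if (stats::runif(1) < p) {
        # choose which bond ruptured, proportionally to its rate
        w <- c(r_dom, r_tet)
        if (any(!is.finite(w))) w <- as.numeric(!is.finite(w))
        j <- sample.int(n_dom + 1L, 1L, prob = w)
        if (j > n_dom) {
          detached <- TRUE
          ev_t <- c(ev_t, t_i)
          ev_z <- c(ev_z, z)
          ev_x <- c(ev_x, x)
          ev_F <- c(ev_F, F)
          ev_d <- c(ev_d, "tether")
          ev_type <- c(ev_type, "detach")
          x <- z
          F <- 0
        } else {
          folded[j] <- FALSE
          ev_t <- c(ev_t, t_i)
          ev_z <- c(ev_z, z)
          ev_x <- c(ev_x, x)
          ev_F <- c(ev_F, F)
          ev_d <- c(ev_d, names_dom[j])
          ev_type <- c(ev_type, "unfold")
          Lc <- Lc + (L_unf[j] - d_NC[j])
          x <- solve_force_balance(z, Lc, a, k_c, x0 = x)
          F <- k_c * (z - x)
        }
      }
      remaining <- remaining - dt_sub
    }
    ext[i] <- x
    frc[i] <- F
    x_prev <- x
  }

  # instrumental artifacts, applied to the recorded trace only
  if (noise$adhesion_amplitude > 0) {
    amp <- noise$adhesion_amplitude * stats::runif(1, 0.5, 1.5)
    frc <- frc + amp * exp(-ext / noise$adhesion_range)
  }
  if (noise$baseline_drift != 0) frc <- frc + noise$baseline_drift * ext
  if (noise$force_noise_sd > 0) {
    frc <- frc + stats::rnorm(n_steps, 0, noise$force_noise_sd)
  }

  curve <- force_curve(
    extension = ext, force = frc,
    speed = v, spring_constant = protocol$cantilever_k_N_m,
    temperature = protocol$temperature, curve_id = curve_id
  )
  events <- if (length(ev_t)) {
    data.frame(time_s = ev_t, piezo_nm = ev_z, extension_nm = ev_x,
               force_pN = ev_F, domain = ev_d, type = ev_type,
               stringsAsFactors = FALSE)
  } else {
    empty_event_log()
  }
  list(curve = curve, events = events)
}

#' Simulate a full pulling experiment
#'
#' A sequence of `n_ramps` independent ramps. Each ramp picks up a molecule
#' with `noise$pickup_probability`; on pickup, a uniformly random contiguous
#' C-terminal sub-construct (1 to all domains) is tethered, emulating the
#' tip grabbing the surface-anchored chain at a random position. Ramps
#' without pickup yield noise-only traces with empty event logs.
#'
#' @param construct A [construct_spec()].
#' @param protocol A [pulling_protocol()].
#' @param noise A [noise_model()].
#' @param n_ramps Number of ramps (>= 1).
#' @param seed Integer seed driving all randomness of the experiment.
#' @param variable_pickup If `FALSE`, every pickup tethers the full
#'   construct (useful for controlled recovery studies).
#' @return A list of per-ramp results as returned by [simulate_pull()], with
#'   curve ids `ramp0001`, `ramp0002`, ...
#' @export
simulate_experiment <- function(construct, protocol, noise = noise_model(),
                                n_ramps = 100, seed = NULL,
                                variable_pickup = TRUE) {
  stopifnot(n_ramps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_dom <- length(construct$domains)
  lapply(seq_len(n_ramps), function(i) {
    id <- sprintf("ramp%04d", i)
    if (stats::runif(1) < noise$pickup_probability) {
      sub <- if (variable_pickup) {
        m <- sample.int(n_dom, 1L)
        construct_spec(construct$domains[(n_dom - m + 1L):n_dom],
                       linker_contour = construct$linker_contour,
                       persistence_length = construct$persistence_length)
      } else {
        construct
      }
      simulate_pull(sub, protocol, noise, seed = NULL, curve_id = id)
    } else {
      # noise-only trace: tip never attaches; extension equals piezo travel
      dt <- protocol$sample_interval
      n_steps <- ceiling(protocol$ramp_length / (protocol$speed * dt))
      ext <- protocol$speed * dt * seq_len(n_steps)
      frc <- numeric(n_steps)
      if (noise$adhesion_amplitude > 0) {
        amp <- noise$adhesion_amplitude * stats::runif(1, 0.5, 1.5)
        frc <- frc + amp * exp(-ext / noise$adhesion_range)
      }
      if (noise$force_noise_sd > 0) {
        frc <- frc + stats::rnorm(n_steps, 0, noise$force_noise_sd)
      }
      list(
        curve = force_curve(ext, frc, speed = protocol$speed,
                            spring_constant = protocol$cantilever_k_N_m,
                            temperature = protocol$temperature,
                            curve_id = id),
        events = empty_event_log()
      )
    }
  })
}

#' Sample rupture forces at constant loading rate
#'
#' I.i.d. rupture forces of a Bell-model bond under an idealised constant
#' loading rate, drawn by exact inverse-CDF sampling from
#' [rupture_force_distribution()].
#'
#' @param params A [bell_params()] object.
#' @param loading_rate Loading rate in pN/s (> 0).
#' @param n Number of draws (>= 1).
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return Numeric vector of `n` rupture forces in pN.
#' @examples
#' f <- simulate_constant_loading(bell_params(0.003, 0.2), 1.5e5, 1000, seed = 1)
#' mean(f)
#' @export
simulate_constant_loading <- function(params, loading_rate, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- rupture_force_distribution(loading_rate, params)
  d$quantile(stats::runif(n))
}
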