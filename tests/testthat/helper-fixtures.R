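# Shared fixtures for the test suite. Everything is generated in code.

kT298 <- smfstools::thermal_energy(298)

# noise-free measurement model with an effectively unbreakable tether
# (vanishing zero-force rate and near-zero transition distance, so the
# tether hazard stays negligible even at diverging forces)
quiet_noise <- function() {
  noise_model(force_noise_sd = 0, adhesion_amplitude = 0,
              tether_kinetics = bell_params(1e-30, 1e-6),
              pickup_probability = 1)
}

# single-domain construct on an inert linker; first rupture only
single_rii_construct <- function(linker = 33.6) {
  construct_spec(list(domain_preset("RII")), linker_contour = linker)
}

# independent first-passage oracle: survival along the deterministic
# force ramp by rectangle-rule quadrature of the Bell hazard
first_rupture_oracle <- function(linker = 33.6, speed = 1000,
                                 k_c = 150, Lp = 0.3, t_max = 0.12,
                                 dt = 1e-4, kinetics = bell_params(0.003, 0.2)) {
  Lc <- linker + domain_preset("RII")$folded_NC
  a <- kT298 / Lp
  tgrid <- seq(dt, t_max, by = dt)
  Fdet <- vapply(tgrid, function(t) {
    z <- speed * t
    x <- stats::uniroot(function(x) {
      x + a * (0.25 * (1 - x / Lc)^-2 - 0.25 + x / Lc) / k_c - z
    }, c(0, Lc * (1 - 1e-9)), tol = 1e-12)$root
    k_c * (z - x)
  }, numeric(1))
  k <- kinetics$k_u0 * exp(Fdet * kinetics$x_u / kT298)
  H <- cumsum(k) * dt
  S <- exp(-c(0, H[-length(H)]))
  w <- k * S * dt
  sum(Fdet * w) / sum(w)
}

# exact noiseless WLC force segment as a force_curve
wlc_segment_curve <- function(Lc = 40, Lp = 0.3, x = seq(2, 36, by = 0.25),
                              baseline = 0) {
  p <- wlc_params(Lp, Lc)
  force_curve(x, wlc_force(x, p) + baseline, speed = 1000,
              spring_constant = 0.15, curve_id = "segment")
}
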