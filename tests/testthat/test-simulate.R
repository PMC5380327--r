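# Monte Carlo pulling simulator: deterministic limits, first-passage
# statistics against an independent quadrature oracle, event-log
# invariants, pickup statistics and the constant-loading sampler.

test_that("without rupture the trace is the exact WLC/cantilever balance", {
  con <- single_rii_construct(linker = 300)
  # kinetics that never fire: replace the domain with an inert one
  con$domains[[1]] <- domain_spec("RII", 104, 4.8, 38,
                                  bell_params(1e-30, 1e-6))
  prot <- pulling_protocol(speed = 1000, ramp_length = 280)
  sim <- simulate_pull(con, prot, quiet_noise(), seed = 1)
  expect_identical(nrow(sim$events), 0L)
  Lc <- 300 + 4.8
  p <- wlc_params(0.3, Lc)
  x <- sim$curve$extension
  f <- sim$curve$force
  # force equals the WLC force at the recorded extension ...
  expect_equal(f[x > 0], wlc_force(x[x > 0], p), tolerance = 1e-6)
  # ... and the series balance z = x + F/k_c holds on the piezo grid
  z <- 1000 * prot$sample_interval * seq_along(x)
  expect_equal(x + f / 150, z, tolerance = 1e-6)
})

test_that("simulation is deterministic for a fixed seed", {
  con <- construct_preset("RII8")
  prot <- pulling_protocol(speed = 1000)
  expect_identical(simulate_pull(con, prot, seed = 5),
                   simulate_pull(con, prot, seed = 5))
  expect_identical(
    simulate_experiment(con, prot, n_ramps = 15, seed = 3),
    simulate_experiment(con, prot, n_ramps = 15, seed = 3)
  )
  expect_identical(
    simulate_constant_loading(bell_params(0.003, 0.2), 1e5, 50, seed = 2),
    simulate_constant_loading(bell_params(0.003, 0.2), 1e5, 50, seed = 2)
  )
})

test_that("first-rupture forces match the quadrature first-passage oracle", {
  con <- single_rii_construct(linker = 33.6)
  prot <- pulling_protocol(speed = 1000, ramp_length = 120)
  set.seed(11)
  f <- replicate(800, {
    ev <- simulate_pull(con, prot, quiet_noise())$events
    ev$force_pN[ev$type == "unfold"][1]
  })
  expect_false(anyNA(f))
  oracle <- first_rupture_oracle(linker = 33.6, speed = 1000)
  # MC standard error of the mean is ~0.9 pN here
  expect_lt(abs(mean(f) - oracle), 4)
})

test_that("event logs satisfy their structural invariants", {
  con <- construct_preset("RII8")
  prot <- pulling_protocol(speed = 1000)
  for (seed in 1:10) {
    sim <- simulate_pull(con, prot, quiet_noise(), seed = seed)
    ev <- sim$events
    expect_lte(sum(ev$type == "unfold"), length(con$domains))
    expect_true(all(diff(ev$time_s) >= 0))
    expect_lte(sum(ev$type == "detach"), 1L)
    if (any(ev$type == "detach")) {
      expect_identical(ev$type[nrow(ev)], "detach")
    }
  }
  # force is continuous between events and drops strictly at each event
  noise0 <- noise_model(force_noise_sd = 0, adhesion_amplitude = 0,
                        pickup_probability = 1)
  sim <- simulate_pull(con, prot, noise0, seed = 4)
  f <- sim$curve$force
  ev_steps <- unique(round(sim$events$time_s / prot$sample_interval))
  jumps <- diff(f)
  at_event <- seq_along(jumps) %in% (ev_steps - 1)
  expect_true(all(jumps[at_event] < 0))
  # between events the quasi-static loading is smooth: the per-sample rise
  # is bounded by the series stiffness times the 0.5 nm piezo step
  expect_lt(max(abs(jumps[!at_event])), 40)
})

test_that("mean rupture force is non-decreasing in pulling speed", {
  con <- construct_preset("RII8")
  means <- vapply(c(50, 200, 1000, 4880), function(v) {
    set.seed(21)
    f <- unlist(lapply(1:25, function(i) {
      ev <- simulate_pull(con, pulling_protocol(speed = v), quiet_noise())$events
      ev$force_pN[ev$type == "unfold"]
    }))
    mean(f)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("molecule pickup follows the configured probability", {
  con <- construct_preset("RII8")
  prot <- pulling_protocol(speed = 4880)   # fast ramps keep this test light
  none <- simulate_experiment(con, prot,
                              noise_model(pickup_probability = 0),
                              n_ramps = 30, seed = 1)
  expect_true(all(vapply(none, function(s) nrow(s$events) == 0L, logical(1))))

  sims <- simulate_experiment(con, prot,
                              noise_model(pickup_probability = 0.03),
                              n_ramps = 2000, seed = 1)
  frac <- mean(vapply(sims, function(s) any(s$events$type == "unfold"),
                      logical(1)))
  ci <- 0.03 + c(-1, 1) * 2.576 * sqrt(0.03 * 0.97 / 2000)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("a misfolded GFP contributes contour but no event", {
  con <- construct_preset("RII8-GFP")
  prot <- pulling_protocol(speed = 1000)
  noise <- quiet_noise()
  noise$gfp_misfold_probability <- 1
  sim <- simulate_pull(con, prot, noise, seed = 2)
  expect_identical(sum(sim$events$domain == "GFP"), 0L)
  expect_identical(sum(sim$events$type == "unfold"), 8L)
  # the weakest (GFP) domain unfolds first when it is folded
  noise$gfp_misfold_probability <- 0
  for (seed in 1:8) {
    ev <- simulate_pull(con, prot, noise, seed = seed)$events
    g <- which(ev$domain == "GFP")
    rii <- which(ev$domain == "RII")
    if (length(rii) >= 5 && length(g)) {
      expect_true(all(g < min(rii)))
    }
  }
})

test_that("constant-loading sampler reproduces the analytic distribution", {
  b <- bell_params(0.003, 0.2)
  d <- rupture_force_distribution(1.5e5, b)
  f <- simulate_constant_loading(b, 1.5e5, 1e4, seed = 2)
  ks <- suppressWarnings(stats::ks.test(f, d$cdf))
  expect_lt(unname(ks$statistic), 0.02)
  # histogram mode near the analytic mode
  s <- force_summary(f, "mode")
  expect_lt(abs(s$force - d$mode), 5)
  # large-x_u limit concentrates near zero force
  soft <- simulate_constant_loading(bell_params(0.003, 20), 1e3, 1000,
                                    seed = 3)
  expect_lt(stats::quantile(soft, 0.99), 5)
})

test_that("halving the sampling interval leaves rupture statistics unchanged", {
  con <- construct_preset("RII8")
  pull_forces <- function(dt, seed) {
    prot <- pulling_protocol(speed = 1000, sample_interval = dt)
    set.seed(seed)
    unlist(lapply(1:50, function(i) {
      ev <- simulate_pull(con, prot, quiet_noise())$events
      ev$force_pN[ev$type == "unfold"]
    }))
  }
  a <- pull_forces(5e-4, 31)
  b <- pull_forces(2.5e-4, 32)
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})
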