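# Population-level statistics: force summaries, per-curve cv, the
# Bell-Evans loading-rate fit and condition comparison.

test_that("force summaries report mean, sample sd and histogram mode", {
  s <- force_summary(c(300, 350, 400))
  expect_equal(s$force, 350)
  expect_equal(s$sd, 50)
  expect_identical(s$n, 3L)
  expect_identical(force_summary(rep(123, 5))$sd, 0)
  expect_error(force_summary(c(300, 350), "mode"), "at least 20")
  # histogram mode of a large sample sits at the analytic mode
  b <- bell_params(0.003, 0.2)
  f <- simulate_constant_loading(b, 1.5e5, 1e4, seed = 4)
  m <- force_summary(f, "mode")
  expect_lt(abs(m$force - rupture_force_distribution(1.5e5, b)$mode), 5)
})

test_that("per-curve cv measures within-curve force heterogeneity", {
  tab <- data.frame(
    curve_id = rep(c("a", "b"), c(5, 5)),
    Fu_pN = c(300, 350, 400, 350, 350, rep(200, 5)),
    label = "RII"
  )
  out <- cv_per_curve(tab, min_peaks = 5)
  expect_identical(out$n_curves, 2L)
  a_cv <- out$curves$cv[out$curves$curve_id == "a"]
  expect_equal(a_cv, sd(c(300, 350, 400, 350, 350)) / 350, tolerance = 1e-12)
  expect_identical(out$curves$cv[out$curves$curve_id == "b"], 0)
  # scale invariance: multiplying all forces by a constant leaves cv fixed
  tab2 <- tab
  tab2$Fu_pN <- tab2$Fu_pN * 3.7
  expect_equal(cv_per_curve(tab2, 5)$curves$cv, out$curves$cv,
               tolerance = 1e-12)
  # no qualifying curves is flagged, not an error
  none <- cv_per_curve(tab, min_peaks = 6)
  expect_identical(none$n_curves, 0L)
  expect_true(is.na(none$cv_mean))
})

test_that("heterogeneous repeats raise the per-curve cv", {
  prot <- pulling_protocol(speed = 1000)
  cv_of <- function(con, seed) {
    set.seed(seed)
    sims <- lapply(1:30, function(i) {
      simulate_pull(con, prot, curve_id = sprintf("c%02d", i))
    })
    cv_per_curve(analyze_experiment(sims), min_peaks = 5)$cv_mean
  }
  cv_homog <- cv_of(construct_preset("RII8"), 9)
  cv_mixed <- cv_of(construct_preset("MhLapRII8"), 9)
  expect_gt(cv_mixed, cv_homog)
})

test_that("Bell-Evans fits invert exact Evans-model inputs", {
  b <- bell_params(0.003, 0.2)
  r <- 150 * c(50, 200, 1000, 4880)
  ss <- speed_series(c(50, 200, 1000, 4880), 0.15,
                     as.numeric(evans_force(r, b)))
  fit <- fit_bell_evans(ss)
  expect_equal(fit$x_u, 0.2, tolerance = 1e-10)
  expect_equal(fit$k_u0, 0.003, tolerance = 1e-8)
  expect_equal(fit$slope, kT298 / 0.2, tolerance = 1e-10)
  # two points: the line passes through both exactly
  ss2 <- ss[1:2, ]
  fit2 <- fit_bell_evans(ss2)
  pred <- fit2$intercept + fit2$slope * log(ss2$loading_rate_pN_s)
  expect_equal(pred, ss2$force_pN, tolerance = 1e-10)
  # decreasing forces are unphysical
  bad <- speed_series(c(50, 4880), 0.15, c(300, 200))
  expect_error(fit_bell_evans(bad), "slope")
  expect_error(fit_bell_evans(ss[1, ]), "2 distinct")
})

test_that("Bell parameters are recovered from sampled rupture forces", {
  b <- bell_params(0.003, 0.2)
  set.seed(1)
  speeds <- c(50, 200, 1000, 4880)
  rows <- lapply(speeds, function(v) {
    f <- simulate_constant_loading(b, 150 * v, 800)
    s <- force_summary(f, "mode")
    data.frame(v = v, force = s$force)
  })
  rows <- do.call(rbind, rows)
  fit <- fit_bell_evans(speed_series(rows$v, 0.15, rows$force))
  expect_lt(abs(fit$x_u / 0.2 - 1), 0.15)
  expect_gt(fit$k_u0, 0.003 / 2)
  expect_lt(fit$k_u0, 0.003 * 2)
})

test_that("the full pipeline recovers the generative transition distance", {
  con <- construct_preset("RII8")
  set.seed(41)
  rows <- lapply(c(50, 200, 1000, 4880), function(v) {
    prot <- pulling_protocol(speed = v)
    sims <- lapply(1:25, function(i) {
      simulate_pull(con, prot, curve_id = sprintf("v%d_%02d", v, i))
    })
    tab <- analyze_experiment(sims)
    f <- tab$Fu_pN[tab$label == "RII"]
    s <- force_summary(f, "mode")
    data.frame(v = v, force = s$force, n = s$n)
  })
  rows <- do.call(rbind, rows)
  fit <- fit_bell_evans(speed_series(rows$v, 0.15, rows$force))
  # wider band than the idealised sampler: the nominal loading rate k_c v
  # overstates the true WLC loading rate, as in the published estimator
  expect_lt(abs(fit$x_u / 0.2 - 1), 0.25)
})

test_that("condition comparison reports force differences and cv contrast", {
  a <- list(forces = c(300, 350, 400))
  expect_identical(compare_conditions(a, a)$delta_force, 0)
  # a strong-vs-weak construction has the built-in sign
  strong <- list(forces = simulate_constant_loading(bell_params(0.003, 0.2),
                                                    1.5e5, 500, seed = 6))
  weak <- list(forces = simulate_constant_loading(bell_params(0.3, 0.2),
                                                  1.5e5, 500, seed = 7))
  cmp <- compare_conditions(strong, weak)
  expect_gt(cmp$delta_force, 0)
  # pooled standard error agrees with a bootstrap on small samples
  set.seed(8)
  fa <- rnorm(40, 350, 45)
  fb <- rnorm(35, 250, 55)
  cmp2 <- compare_conditions(list(forces = fa), list(forces = fb))
  boot <- replicate(2000, mean(sample(fa, replace = TRUE)) -
                      mean(sample(fb, replace = TRUE)))
  expect_lt(abs(cmp2$se_delta / sd(boot) - 1), 0.10)
})
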