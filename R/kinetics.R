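# Population-level analysis: representative unfolding forces (mean or
# histogram mode), per-curve relative standard deviation of unfolding
# forces, the Bell-Evans loading-rate fit for x_u and k_u0, and the
# comparison of measurement conditions (e.g. calcium levels).

#' Representative unfolding force of a sample
#'
#' Summarises a set of unfolding forces either by the arithmetic mean
#' (with sample standard deviation, the usual mean +/- sd reporting) or by
#' the histogram mode: a Gaussian fitted to a Freedman-Diaconis histogram,
#' matching the most-probable-force quantity of the Evans loading-rate
#' relation.
#'
#' @param forces Numeric vector of forces in pN (length >= 1; the mode
#'   estimator requires >= 20).
#' @param estimator `"mean"` or `"mode"`.
#' @return A list: `force` (representative force, pN), `sd` (sample sd),
#'   `n`, `estimator`.
#' @examples
#' force_summary(c(300, 350, 400))
#' @export
force_summary <- function(forces, estimator = c("mean", "mode")) {
  estimator <- match.arg(estimator)
  stopifnot(is.numeric(forces), length(forces) >= 1L)
  s <- if (length(forces) >= 2L) stats::sd(forces) else 0
  if (estimator == "mean") {
    return(list(force = mean(forces), sd = s, n = length(forces),
                estimator = "mean"))
  }
  if (length(forces) < 20L) {
    stop("the mode estimator requires at least 20 forces")
  }
  h <- graphics::hist(forces, breaks = "FD", plot = FALSE)
  mids <- h$mids
  cnt <- h$counts
  # fit the Gaussian to the contiguous peak region only (counts >= 40% of
  # the maximum), so that skewed tails do not bias the mode estimate
  i_max <- which.max(cnt)
  lo <- i_max; while (lo > 1L && cnt[lo - 1L] >= 0.4 * cnt[i_max]) lo <- lo - 1L
  hi <- i_max; while (hi < length(cnt) && cnt[hi + 1L] >= 0.4 * cnt[i_max]) hi <- hi + 1L
  sel <- lo:hi
  mode_f <- mids[i_max]
  if (length(sel) >= 4L) {
    mids_s <- mids[sel]
    cnt_s <- cnt[sel]
    fit <- minpack.lm::nls.lm(
      par = c(amp = max(cnt_s), mu = mids[i_max], sigma = s),
      fn = function(par) {
        cnt_s - par[1] * exp(-(mids_s - par[2])^2 / (2 * par[3]^2))
      },
      lower = c(0, min(mids), diff(range(mids)) / 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (fit$info %in% 1:4) mode_f <- fit$par[["mu"]]
  }
  list(force = mode_f, sd = s, n = length(forces), estimator = "mode")
}

#' Per-curve relative standard deviation of unfolding forces
#'
#' For each curve of a classified event table with at least `min_peaks`
#' peaks of the given label, computes the mean force mu, sample sd sigma and
#' cv = sigma/mu of those peaks, then summarises cv across qualifying
#' curves. The cv probes the heterogeneity of the repeats within one
#' polyprotein chain.
#'
#' @param table A classified event table (see [classify_peaks()]).
#' @param min_peaks Minimum labelled peaks per curve (default 5).
#' @param label Peak label used (default `"RII"`).
#' @return A list: `curves` (data frame `curve_id`, `mu`, `sigma`, `cv`,
#'   `n`), `cv_mean`, `cv_sd`, `n_curves`. With no qualifying curve the
#'   data frame is empty and the summaries are `NA` (flagged via
#'   `n_curves = 0`).
#' @export
cv_per_curve <- function(table, min_peaks = 5L, label = "RII") {
  stopifnot(is.data.frame(table), min_peaks >= 1)
  sel <- table[!is.na(table$label) & table$label == label, , drop = FALSE]
  per <- lapply(split(sel$Fu_pN, sel$curve_id), function(f) {
    if (length(f) < min_peaks) return(NULL)
    mu <- mean(f)
    sigma <- if (length(f) >= 2L) stats::sd(f) else 0
    data.frame(mu = mu, sigma = sigma, cv = sigma / mu, n = length(f))
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) {
    return(list(curves = data.frame(curve_id = character(0), mu = numeric(0),
                                    sigma = numeric(0), cv = numeric(0),
                                    n = integer(0)),
                cv_mean = NA_real_, cv_sd = NA_real_, n_curves = 0L))
  }
  curves <- do.call(rbind, per)
  curves <- cbind(curve_id = names(per), curves, stringsAsFactors = FALSE)
  rownames(curves) <- NULL
  list(curves = curves, cv_mean = mean(curves$cv),
       cv_sd = if (nrow(curves) >= 2L) stats::sd(curves$cv) else NA_real_,
       n_curves = nrow(curves))
}

#' Per-speed series of representative unfolding forces
#'
#' One row per pulling speed: the speed, cantilever spring constant, the
#' nominal loading rate `r = k_c v`, and the representative unfolding force
#' with spread and sample size.
#'
#' @param speed Pulling speeds in nm/s.
#' @param spring_constant Cantilever spring constant(s), unit per `k_unit`.
#' @param force Representative force per speed, pN.
#' @param force_sd Force spread per speed, pN (optional).
#' @param n Sample size per speed (optional).
#' @param k_unit `"N/m"` (default) or `"pN/nm"`.
#' @return A data frame of class `"speed_series"` with columns
#'   `speed_nm_s`, `k_pN_nm`, `loading_rate_pN_s`, `force_pN`, `force_sd`,
#'   `n`.
#' @examples
#' speed_series(c(50, 200, 1000, 4880), 0.15, c(230, 260, 300, 340))
#' @export
speed_series <- function(speed, spring_constant, force, force_sd = NA_real_,
                         n = NA_integer_, k_unit = "N/m") {
  stopifnot(all(speed > 0), all(spring_constant > 0),
            length(force) == length(speed))
  k_pN_nm <- convert_spring_constant(spring_constant,
                                     match.arg(k_unit, c("N/m", "pN/nm")),
                                     "pN/nm")
  out <- data.frame(
    speed_nm_s = speed,
    k_pN_nm = rep_len(k_pN_nm, length(speed)),
    loading_rate_pN_s = rep_len(k_pN_nm, length(speed)) * speed,
    force_pN = force,
    force_sd = rep_len(force_sd, length(speed)),
    n = rep_len(n, length(speed))
  )
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Bell-Evans fit of the loading-rate dependence
#'
#' Ordinary least squares of the representative unfolding force on the log
#' nominal loading rate,
#' \deqn{F(r) = \frac{k_B T}{x_u} \ln\!\left(\frac{r\,x_u}{k_B T k_u^0}\right),}
#' recovering the distance to the transition state from the slope
#' (`x_u = k_B T / slope`) and the zero-force unfolding rate from the
#' intercept. Standard errors come from first-order propagation of the OLS
#' covariance; for `k_u0` the error is reported on the log scale (a
#' multiplicative factor).
#'
#' @param series A [speed_series()] data frame (>= 2 distinct loading
#'   rates), or any data frame with columns `loading_rate_pN_s` and
#'   `force_pN`.
#' @param temperature Absolute temperature in K.
#' @return An object of class `"bell_evans_fit"`: `params` (a
#'   [bell_params()]), `x_u`, `k_u0`, `x_u_se`, `log_k_u0_se`, `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
fit_bell_evans <- function(series, temperature = 298) {
  stopifnot(is.data.frame(series),
            all(c("loading_rate_pN_s", "force_pN") %in% names(series)))
  r <- series$loading_rate_pN_s
  f <- series$force_pN
  if (length(unique(r)) < 2L) {
    stop("at least 2 distinct loading rates are required")
  }
  kT <- thermal_energy(temperature)
  fit <- stats::lm(f ~ log(r))
  cf <- stats::coef(fit)
  slope <- cf[[2]]
  b0 <- cf[[1]]
  if (slope <= 0) {
    stop("non-positive slope of force vs log loading rate (unphysical x_u)")
  }
  x_u <- kT / slope
  k_u0 <- (x_u / kT) * exp(-b0 / slope)

  # vcov warns on zero-residual (saturated) fits; their SEs are reported
  # as-is (zero/NaN) rather than refused
  V <- suppressWarnings(stats::vcov(fit))
  se_s <- sqrt(V[2, 2])
  se_b <- sqrt(V[1, 1])
  cov_bs <- V[1, 2]
  x_u_se <- kT * se_s / slope^2
  # log k_u0 = -log(slope) - b0/slope; gradient wrt (b0, slope)
  g <- c(-1 / slope, -1 / slope + b0 / slope^2)
  log_k_u0_var <- g[1]^2 * se_b^2 + g[2]^2 * se_s^2 + 2 * g[1] * g[2] * cov_bs
  log_k_u0_se <- sqrt(max(log_k_u0_var, 0))

  structure(
    list(params = bell_params(k_u0, x_u, temperature),
         x_u = x_u, k_u0 = k_u0, x_u_se = x_u_se,
         log_k_u0_se = log_k_u0_se, slope = slope, intercept = b0,
         r_squared = {
           sst <- sum((f - mean(f))^2)
           if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
         },
         n = length(r)),
    class = "bell_evans_fit"
  )
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat(sprintf(
    "Bell-Evans fit (n = %d): x_u = %.3g +/- %.2g nm, k_u0 = %.3g 1/s (x/ %.3g)\n",
    x$n, x$x_u, x$x_u_se, x$k_u0, exp(x$log_k_u0_se)))
  invisible(x)
}

#' Compare two measurement conditions
#'
#' Difference of representative unfolding forces between two conditions
#' (e.g. two free-calcium concentrations) with its pooled standard error,
#' plus the contrast of mean per-curve cv when supplied.
#'
#' @param a,b Lists describing each condition: `forces` (numeric vector,
#'   required) and optionally `cv` (a [cv_per_curve()] result).
#' @param estimator Passed to [force_summary()].
#' @return A list: `force_a`, `force_b`, `delta_force` (a - b), `se_delta`
#'   (pooled), `cv_a`, `cv_b`, `delta_cv` (NA when cv not supplied).
#' @export
compare_conditions <- function(a, b, estimator = "mean") {
  stopifnot(is.list(a), is.list(b),
            is.numeric(a$forces), length(a$forces) >= 1L,
            is.numeric(b$forces), length(b$forces) >= 1L)
  sa <- force_summary(a$forces, estimator)
  sb <- force_summary(b$forces, estimator)
  se <- sqrt(sa$sd^2 / sa$n + sb$sd^2 / sb$n)
  cv_a <- if (!is.null(a$cv)) a$cv$cv_mean else NA_real_
  cv_b <- if (!is.null(b$cv)) b$cv$cv_mean else NA_real_
  list(force_a = sa$force, force_b = sb$force,
       delta_force = sa$force - sb$force, se_delta = se,
       cv_a = cv_a, cv_b = cv_b, delta_cv = cv_a - cv_b)
}
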