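# Curve-level analysis of sawtooth force-extension traces: baseline
# estimation, rupture-peak detection, per-peak worm-like-chain fitting,
# contour-length accounting between consecutive peaks, and peak
# classification (domain unfolding vs nonspecific adhesion vs final
# detachment).

#' Force-extension curve
#'
#' One pulling ramp: tip-sample separation (extension, nm) versus force
#' (pN), with acquisition metadata. Extension must be non-decreasing; force
#' is positive when pulling away from the surface.
#'
#' @param extension Extension in nm, non-decreasing, length >= 2.
#' @param force Force in pN, same length.
#' @param speed Pulling speed in nm/s.
#' @param spring_constant Cantilever spring constant in N/m.
#' @param temperature Absolute temperature in K.
#' @param curve_id Identifier string.
#' @return An object of class `"force_curve"`.
#' @export
force_curve <- function(extension, force, speed = NA_real_,
                        spring_constant = NA_real_, temperature = 298,
                        curve_id = "curve") {
  stopifnot(is.numeric(extension), is.numeric(force))
  if (length(extension) != length(force)) {
    stop("extension and force must have equal length")
  }
  if (length(extension) < 2L) stop("a curve needs at least 2 samples")
  if (any(diff(extension) < 0)) stop("extension must be non-decreasing")
  structure(
    list(extension = extension, force = force,
         metadata = list(speed = speed, spring_constant = spring_constant,
                         temperature = temperature, curve_id = curve_id)),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("Force curve '%s': %d samples, %.1f-%.1f nm, v = %s nm/s\n",
              x$metadata$curve_id, length(x$force), min(x$extension),
              max(x$extension), format(x$metadata$speed)))
  invisible(x)
}

# light smoothing used by baseline and peak detection
smooth_force <- function(force, k = 5L) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(force) < k) return(force)
  as.numeric(stats::filter(force, rep(1 / k, k), sides = 2)) ->
    out
  # fill filter edge NAs with the raw values
  na <- is.na(out)
  out[na] <- force[na]
  out
}

#' Estimate the force baseline of a curve
#'
#' The baseline is the median force over the post-detachment tail (by
#' default the final 10% of the extension range). If the tail is not flat
#' (its spread is large compared to the point-to-point noise, e.g. when the
#' molecule is still attached at the ramp end), the estimator falls back to
#' the mode of the force histogram of the whole curve, which is dominated by
#' baseline samples in typical traces.
#'
#' @param curve A [force_curve()].
#' @param tail_fraction Fraction of the extension range treated as tail.
#' @return Baseline force in pN.
#' @export
estimate_baseline <- function(curve, tail_fraction = 0.1) {
  stopifnot(inherits(curve, "force_curve"),
            tail_fraction > 0, tail_fraction < 1)
  x <- curve$extension
  f <- curve$force
  cut <- max(x) - tail_fraction * diff(range(x))
  tail_f <- f[x >= cut]
  noise_sd <- stats::mad(diff(f)) / sqrt(2)
  if (length(tail_f) >= 10L &&
      stats::sd(tail_f) <= max(3 * noise_sd, 1e-12)) {
    return(stats::median(tail_f))
  }
  if (stats::sd(f) == 0) return(f[1])
  d <- stats::density(f, n = 512)
  d$x[which.max(d$y)]
}

#' Detect rupture peaks in a force-extension curve
#'
#' Calls local maxima of the (lightly smoothed) force that rise at least
#' `min_force` above the baseline and are followed, within `min_separation`
#' nm, by a force drop of at least `min_drop`. Accepted peaks are separated
#' by at least `min_separation` nm (taller peaks win). The unfolding force
#' of each peak is the raw peak force minus the baseline.
#'
#' @param curve A [force_curve()].
#' @param min_force Minimum peak height above baseline, pN.
#' @param min_drop Minimum force drop after the peak, pN.
#' @param min_separation Minimum extension separation between peaks, nm
#'   (also the window within which the drop must occur).
#' @param baseline Baseline force in pN; estimated with
#'   [estimate_baseline()] when `NULL`.
#' @param smooth Moving-average window (samples) used for peak finding.
#' @return A data frame of class `"peak_calls"`, ordered by extension, with
#'   columns `peak_index`, `peak_extension`, `peak_force_raw`, `baseline`,
#'   `unfolding_force`; zero rows when nothing is found.
#' @export
detect_peaks <- function(curve, min_force = 50, min_drop = 50,
                         min_separation = 10, baseline = NULL,
                         smooth = 5L) {
  stopifnot(inherits(curve, "force_curve"),
            min_force >= 0, min_drop >= 0, min_separation > 0)
  if (is.null(baseline)) baseline <- estimate_baseline(curve)
  x <- curve$extension
  f <- curve$force
  fs <- smooth_force(f, smooth)
  n <- length(fs)

  empty <- data.frame(peak_index = integer(0), peak_extension = numeric(0),
                      peak_force_raw = numeric(0), baseline = numeric(0),
                      unfolding_force = numeric(0))
  class(empty) <- c("peak_calls", "data.frame")
  if (n < 3L) return(empty)

  is_max <- c(FALSE, fs[2:(n - 1)] > fs[1:(n - 2)] &
                fs[2:(n - 1)] >= fs[3:n], FALSE)
  cand <- which(is_max & fs >= baseline + min_force)
  if (!length(cand)) return(empty)

  # require the post-peak drop within min_separation nm
  has_drop <- vapply(cand, function(i) {
    j <- which(x > x[i] & x <= x[i] + min_separation)
    length(j) > 0 && min(fs[j]) <= fs[i] - min_drop
  }, logical(1))
  cand <- cand[has_drop]
  if (!length(cand)) return(empty)

  # non-maximum suppression: tallest first, enforce extension separation
  accepted <- integer(0)
  for (i in cand[order(fs[cand], decreasing = TRUE)]) {
    if (!length(accepted) ||
        all(abs(x[i] - x[accepted]) >= min_separation)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)

  # refine each call to the raw-force maximum near the smoothed maximum
  half <- max(2L, as.integer(smooth))
  refined <- vapply(accepted, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    lo + which.max(f[lo:hi]) - 1L
  }, integer(1))

  out <- data.frame(
    peak_index = refined,
    peak_extension = x[refined],
    peak_force_raw = f[refined],
    baseline = baseline,
    unfolding_force = f[refined] - baseline
  )
  class(out) <- c("peak_calls", "data.frame")
  out
}

#' Fit the worm-like-chain model to one rupture peak
#'
#' Least-squares fit of [wlc_force()] (both contour length and persistence
#' length free) to the rising edge ending at a peak, after subtracting the
#' baseline. The window runs from `start_index` (typically the force
#' minimum after the preceding rupture) to the peak. Fits with too few
#' points, failed convergence, or a contour length not exceeding the peak
#' extension are flagged and excluded from downstream statistics.
#'
#' @param curve A [force_curve()].
#' @param peak One row of a [detect_peaks()] result (data frame or list
#'   with `peak_index` and `baseline`).
#' @param start_index First sample of the fit window.
#' @param min_points Minimum number of window points (default 8).
#' @param temperature Absolute temperature in K (defaults to the curve
#'   metadata).
#' @return An object of class `"wlc_fit_result"`: `contour_length`,
#'   `persistence_length`, `residual` (sum of squared residuals), `window`
#'   (index range), `n_points`, logical `flagged` and a `reason` when
#'   flagged.
#' @export
fit_wlc_peak <- function(curve, peak, start_index = 1L, min_points = 8L,
                         temperature = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(temperature)) {
    temperature <- curve$metadata$temperature
    if (is.null(temperature) || is.na(temperature)) temperature <- 298
  }
  i_peak <- as.integer(peak$peak_index[1])
  base <- as.numeric(peak$baseline[1])
  idx <- seq.int(max(1L, as.integer(start_index)), i_peak)

  flagged_fit <- function(reason) {
    structure(
      list(contour_length = NA_real_, persistence_length = NA_real_,
           residual = NA_real_, window = range(idx),
           n_points = length(idx), flagged = TRUE, reason = reason),
      class = "wlc_fit_result"
    )
  }
  if (length(idx) < min_points) return(flagged_fit("too few points"))

  x <- curve$extension[idx]
  y <- curve$force[idx] - base
  kT <- thermal_energy(temperature)
  x_max <- max(x)
  peak_ext <- curve$extension[i_peak]

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (kT / Lp) * (0.25 * (1 - x / Lc)^-2 - 0.25 + x / Lc),
      start = list(Lc = x_max / 0.9, Lp = 0.3),
      lower = c(Lc = x_max * 1.0001, Lp = 0.02),
      upper = c(Lc = x_max * 20, Lp = 10),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(flagged_fit("no convergence"))
  cf <- stats::coef(fit)
  if (cf[["Lc"]] <= peak_ext) return(flagged_fit("Lc <= peak extension"))
  structure(
    list(contour_length = cf[["Lc"]], persistence_length = cf[["Lp"]],
         residual = sum(stats::resid(fit)^2), window = range(idx),
         n_points = length(idx), flagged = FALSE, reason = NA_character_),
    class = "wlc_fit_result"
  )
}

#' Build the per-curve event table
#'
#' Pairs peak calls with their WLC fits and derives the contour-length
#' increments (`dLc_nm`, successive differences of fitted contour lengths)
#' and unfolding lengths (`dL_nm`, successive differences of peak
#' extensions). Flagged fits propagate as `NA`.
#'
#' @param curve A [force_curve()] (metadata is copied into the table).
#' @param peaks A [detect_peaks()] result.
#' @param fits List of [fit_wlc_peak()] results aligned to the peak rows.
#' @return A data frame with columns `curve_id`, `speed_nm_s`, `k_N_m`,
#'   `peak_idx`, `extension_nm`, `Fu_pN`, `Lc_nm`, `Lp_nm`, `dLc_nm`,
#'   `dL_nm`, `label` (initialised `NA`, see [classify_peaks()]).
#' @export
event_table <- function(curve, peaks, fits) {
  stopifnot(inherits(curve, "force_curve"), is.data.frame(peaks),
            is.list(fits), length(fits) == nrow(peaks))
  n <- nrow(peaks)
  Lc <- vapply(fits, function(f) if (f$flagged) NA_real_ else
    f$contour_length, numeric(1))
  Lp <- vapply(fits, function(f) if (f$flagged) NA_real_ else
    f$persistence_length, numeric(1))
  ext <- peaks$peak_extension
  out <- data.frame(
    curve_id = rep(curve$metadata$curve_id, n),
    speed_nm_s = rep(curve$metadata$speed, n),
    k_N_m = rep(curve$metadata$spring_constant, n),
    peak_idx = seq_len(n),
    extension_nm = ext,
    Fu_pN = peaks$unfolding_force,
    Lc_nm = Lc,
    Lp_nm = Lp,
    dLc_nm = if (n) c(NA_real_, diff(Lc)) else numeric(0),
    dL_nm = if (n) c(NA_real_, diff(ext)) else numeric(0),
    label = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  out
}

#' Classify peaks of an event table
#'
#' Assigns one label per peak:
#' * `"detach"` -- the final peak of each curve (the last drop to baseline,
#'   i.e. rupture of the tip-protein attachment);
#' * `"adhesion"` -- peaks close to the surface (extension within
#'   1.5 x `adhesion_range`) without a WLC-consistent rising edge (flagged
#'   fit);
#' * `"GFP"` -- peaks whose unfolding force is below `gfp_force_max` and
#'   whose unfolding length to the *next* peak (or fitted contour-length
#'   increment) falls in `gfp_band`;
#' * `"RII"` -- everything else (a regular repeat-domain unfolding).
#'
#' @param table An [event_table()] data frame (possibly several curves
#'   row-bound together).
#' @param adhesion_range Adhesion decay length in nm.
#' @param gfp_band Length-2 numeric: unfolding-length band (nm) diagnostic
#'   of GFP.
#' @param gfp_force_max Maximum unfolding force (pN) for a GFP call.
#' @return The table with the `label` column filled.
#' @export
classify_peaks <- function(table, adhesion_range = 15,
                           gfp_band = c(60, 90), gfp_force_max = 150) {
  stopifnot(is.data.frame(table), length(gfp_band) == 2L)
  if (!nrow(table)) return(table)
  for (id in unique(table$curve_id)) {
    rows <- which(table$curve_id == id)
    n <- length(rows)
    lab <- rep("RII", n)
    lab[n] <- "detach"
    for (k in seq_len(n)) {
      if (lab[k] == "detach") next
      r <- rows[k]
      near_surface <- table$extension_nm[r] <= 1.5 * adhesion_range
      if (near_surface && is.na(table$Lc_nm[r])) {
        lab[k] <- "adhesion"
        next
      }
      if (table$Fu_pN[r] < gfp_force_max && k < n) {
        dl_next <- table$extension_nm[rows[k + 1]] - table$extension_nm[r]
        dlc_next <- table$Lc_nm[rows[k + 1]] - table$Lc_nm[r]
        in_band <- function(v) !is.na(v) && v >= gfp_band[1] && v <= gfp_band[2]
        if (in_band(dl_next) || in_band(dlc_next)) lab[k] <- "GFP"
      }
    }
    table$label[rows] <- lab
  }
  table
}

#' Keep curves with enough repeat-domain peaks
#'
#' Sawtooth filter: retains only the curves of a (combined, classified)
#' event table with at least `min_peaks` peaks carrying `label`
#' (default the repeat-domain label `"RII"`). This mirrors the convention of
#' restricting per-curve statistics to curves with five or more
#' repeat-unfolding peaks.
#'
#' @param table A classified event table (see [classify_peaks()]).
#' @param min_peaks Minimum number of labelled peaks per curve (>= 1).
#' @param label Peak label counted towards the threshold.
#' @return The subset of rows belonging to retained curves; the retained
#'   curve ids are available as attribute `"curve_ids"`.
#' @export
sawtooth_filter <- function(table, min_peaks = 5L, label = "RII") {
  stopifnot(is.data.frame(table), min_peaks >= 1)
  counts <- tapply(table$label == label, table$curve_id, sum)
  keep <- names(counts)[!is.na(counts) & counts >= min_peaks]
  out <- table[table$curve_id %in% keep, , drop = FALSE]
  attr(out, "curve_ids") <- keep
  out
}

#' Analyze one force-extension curve end to end
#'
#' Baseline estimation, peak detection, per-peak WLC fits (each window
#' starting at the force minimum after the preceding peak, or at the start
#' of the trace), event-table construction and peak classification.
#'
#' @param curve A [force_curve()].
#' @param min_force,min_drop,min_separation Peak-detection thresholds, see
#'   [detect_peaks()].
#' @param adhesion_range,gfp_band,gfp_force_max Classification parameters,
#'   see [classify_peaks()].
#' @param min_fit_points Minimum number of points per WLC fit window.
#' @param smooth Moving-average window (samples) for peak finding.
#' @return A classified event table (zero rows if no peaks were found); the
#'   peak calls and fit objects are attached as attributes `"peaks"` and
#'   `"fits"`.
#' @export
analyze_curve <- function(curve, min_force = 50, min_drop = 50,
                          min_separation = 10, adhesion_range = 15,
                          gfp_band = c(60, 90), gfp_force_max = 150,
                          min_fit_points = 8L, smooth = 5L) {
  baseline <- estimate_baseline(curve)
  peaks <- detect_peaks(curve, min_force = min_force, min_drop = min_drop,
                        min_separation = min_separation,
                        baseline = baseline, smooth = smooth)
  fs <- smooth_force(curve$force, smooth)
  fits <- lapply(seq_len(nrow(peaks)), function(k) {
    i_peak <- peaks$peak_index[k]
    lo <- if (k == 1L) 1L else peaks$peak_index[k - 1L] + 1L
    seg <- lo:i_peak
    start <- seg[which.min(fs[seg])]
    fit_wlc_peak(curve, peaks[k, ], start_index = start,
                 min_points = min_fit_points)
  })
  tab <- event_table(curve, peaks, fits)
  tab <- classify_peaks(tab, adhesion_range = adhesion_range,
                        gfp_band = gfp_band, gfp_force_max = gfp_force_max)
  attr(tab, "peaks") <- peaks
  attr(tab, "fits") <- fits
  tab
}

#' Analyze a collection of curves
#'
#' Applies [analyze_curve()] to each curve (or each `$curve` of simulator
#' output) and row-binds the classified event tables.
#'
#' @param curves A list of [force_curve()] objects or of
#'   [simulate_pull()] results.
#' @param ... Passed to [analyze_curve()].
#' @return One combined classified event table.
#' @export
analyze_experiment <- function(curves, ...) {
  stopifnot(is.list(curves))
  tabs <- lapply(curves, function(cu) {
    if (!inherits(cu, "force_curve") && !is.null(cu$curve)) cu <- cu$curve
    tab <- analyze_curve(cu, ...)
    attr(tab, "peaks") <- NULL
    attr(tab, "fits") <- NULL
    tab
  })
  do.call(rbind, tabs)
}
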