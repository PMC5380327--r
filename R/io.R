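# File formats and configuration. Curves travel as TSV with '#key=value'
# header lines; spectra as 2-column delimited text; event tables as CSV;
# configuration and kinetics results as JSON.

parse_hash_header <- function(lines) {
  hdr <- lines[startsWith(lines, "#")]
  out <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(kv, 1, eq - 1))
      val <- trimws(substr(kv, eq + 1, nchar(kv)))
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!is.na(num)) num else val
    }
  }
  out
}

#' Write a force curve to a TSV file
#'
#' Tab-separated values with `#key=value` metadata lines
#' (`speed_nm_s`, `k_N_m`, `temperature_K`, `curve_id`) followed by columns
#' `extension_nm` and `force_pN`. Values are written at full double
#' precision so the write/read round trip is lossless.
#'
#' @param curve A [force_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  md <- curve$metadata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#speed_nm_s=%.17g", md$speed),
    sprintf("#k_N_m=%.17g", md$spring_constant),
    sprintf("#temperature_K=%.17g", md$temperature),
    sprintf("#curve_id=%s", md$curve_id),
    "extension_nm\tforce_pN"
  ), con)
  writeLines(sprintf("%.17g\t%.17g", curve$extension, curve$force), con)
  invisible(path)
}

#' Read a force curve from a TSV file
#'
#' Reads the format of [write_force_curve()]. Two coordinate conventions
#' are accepted: a column `extension_nm` (tip-sample separation) is used
#' directly, while a column `piezo_nm` (piezo position) is converted to
#' extension via `x = z - F / k_c` using the header spring constant. Force
#' may be given as `force_pN` or `force_nN` (converted, 1 nN = 1000 pN).
#' The metadata fields `speed_nm_s` and `k_N_m` are mandatory.
#'
#' @param path Input file path.
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  md <- parse_hash_header(lines)
  for (field in c("speed_nm_s", "k_N_m")) {
    if (is.null(md[[field]])) {
      stop("mandatory metadata field '", field, "' missing in ", path)
    }
  }
  body <- lines[!startsWith(lines, "#")]
  dat <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE)
  force <- if ("force_pN" %in% names(dat)) {
    dat$force_pN
  } else if ("force_nN" %in% names(dat)) {
    dat$force_nN * 1000
  } else {
    stop("no force column (force_pN or force_nN) in ", path)
  }
  ext <- if ("extension_nm" %in% names(dat)) {
    dat$extension_nm
  } else if ("piezo_nm" %in% names(dat)) {
    k_pN_nm <- convert_spring_constant(md$k_N_m, "N/m", "pN/nm")
    dat$piezo_nm - force / k_pN_nm
  } else {
    stop("no coordinate column (extension_nm or piezo_nm) in ", path)
  }
  force_curve(
    extension = ext, force = force, speed = md$speed_nm_s,
    spring_constant = md$k_N_m,
    temperature = if (is.null(md$temperature_K)) 298 else md$temperature_K,
    curve_id = if (is.null(md$curve_id)) {
      tools::file_path_sans_ext(basename(path))
    } else {
      as.character(md$curve_id)
    }
  )
}

#' Write / read a thermal-noise spectrum
#'
#' Two-column delimited text (`frequency_Hz`, `amplitude_nm2_Hz`) with
#' `#key=value` metadata lines.
#'
#' @param spectrum A [power_spectrum()].
#' @param path File path.
#' @return `path` invisibly (write); a [power_spectrum()] (read).
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  md <- spectrum$metadata
  for (key in names(md)) {
    writeLines(sprintf("#%s=%s", key, format(md[[key]], digits = 17)), con)
  }
  writeLines("frequency_Hz\tamplitude_nm2_Hz", con)
  writeLines(sprintf("%.17g\t%.17g", spectrum$frequency,
                     spectrum$amplitude), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  md <- parse_hash_header(lines)
  body <- lines[!startsWith(lines, "#")]
  dat <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE)
  power_spectrum(dat$frequency_Hz, dat$amplitude_nm2_Hz, metadata = md)
}

#' Write an event table to CSV
#'
#' @param table An event table data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

config_schema <- list(
  seed = NULL,
  simulation = list(
    construct = list(preset = NULL, linker_contour = NULL,
                     persistence_length = NULL, mhlap_ku0_spread = NULL),
    protocol = list(speed = NULL, cantilever_k = NULL, k_unit = NULL,
                    ramp_length = NULL, sample_interval = NULL,
                    temperature = NULL),
    noise = list(force_noise_sd = NULL, baseline_drift = NULL,
                 adhesion_amplitude = NULL, adhesion_range = NULL,
                 tether_k_u0 = NULL, tether_x_u = NULL,
                 pickup_probability = NULL, gfp_misfold_probability = NULL),
    n_ramps = NULL, variable_pickup = NULL
  ),
  analysis = list(min_force = NULL, min_drop = NULL, min_separation = NULL,
                  adhesion_range = NULL, gfp_band = NULL,
                  gfp_force_max = NULL, min_peaks = NULL,
                  min_fit_points = NULL),
  kinetics = list(estimator = NULL, temperature = NULL),
  paths = list(out_dir = NULL)
)

check_config_keys <- function(cfg, schema, path = "") {
  for (key in names(cfg)) {
    here <- paste0(path, "/", key)
    if (!key %in% names(schema)) {
      stop("unknown configuration key: ", here)
    }
    if (is.list(schema[[key]]) && length(schema[[key]]) &&
        is.list(cfg[[key]])) {
      check_config_keys(cfg[[key]], schema[[key]], here)
    }
  }
  invisible(TRUE)
}

#' Read and validate a run configuration
#'
#' JSON configuration with blocks `simulation` (construct preset, pulling
#' protocol, noise model, ramp count), `analysis` (peak-detection and
#' classification thresholds), `kinetics` and `paths`. A `seed` is
#' mandatory; unknown keys are rejected with the offending key path.
#'
#' @param path JSON file path.
#' @return A named list (class `"run_config"`) of validated settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_config_keys(cfg, config_schema)
  if (is.null(cfg$seed)) stop("configuration must contain a 'seed'")
  if (cfg$seed != round(cfg$seed)) stop("'seed' must be an integer")
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

config_construct <- function(cfg_sim, temperature = 298) {
  cc <- cfg_sim$construct
  preset <- if (is.null(cc$preset)) "RII8" else cc$preset
  extra <- list(temperature = temperature)
  if (!is.null(cc$mhlap_ku0_spread)) {
    extra$mhlap_ku0_spread <- cc$mhlap_ku0_spread
  }
  con <- do.call(construct_preset, c(list(name = preset), extra))
  if (!is.null(cc$linker_contour)) con$linker_contour <- cc$linker_contour
  if (!is.null(cc$persistence_length)) {
    con$persistence_length <- cc$persistence_length
  }
  con
}

config_protocol <- function(cfg_sim) {
  pp <- cfg_sim$protocol
  args <- list(
    speed = if (is.null(pp$speed)) 1000 else pp$speed,
    cantilever_k = if (is.null(pp$cantilever_k)) 0.15 else pp$cantilever_k
  )
  for (key in c("k_unit", "ramp_length", "sample_interval", "temperature")) {
    if (!is.null(pp[[key]])) args[[key]] <- pp[[key]]
  }
  do.call(pulling_protocol, args)
}

config_noise <- function(cfg_sim) {
  nn <- cfg_sim$noise
  args <- list()
  for (key in c("force_noise_sd", "baseline_drift", "adhesion_amplitude",
                "adhesion_range", "pickup_probability",
                "gfp_misfold_probability")) {
    if (!is.null(nn[[key]])) args[[key]] <- nn[[key]]
  }
  if (!is.null(nn$tether_k_u0) || !is.null(nn$tether_x_u)) {
    args$tether_kinetics <- bell_params(
      if (is.null(nn$tether_k_u0)) 1e-5 else nn$tether_k_u0,
      if (is.null(nn$tether_x_u)) 0.15 else nn$tether_x_u
    )
  }
  do.call(noise_model, args)
}
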