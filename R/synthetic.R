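#' Harmonic component of a synthetic temperature signal
#'
#' @param period_hours Period in hours (> 0).
#' @param amplitude Amplitude in deg C (>= 0).
#' @param phase Phase in radians, reduced modulo 2*pi.
#' @return A `harmonic_component` list.
#' @export
harmonic_component <- function(period_hours, amplitude, phase = 0) {
  if (!is.numeric(period_hours) || period_hours <= 0) {
    stop("`period_hours` must be a positive number")
  }
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("`amplitude` must be non-negative")
  }
  structure(
    list(
      period_hours = as.numeric(period_hours),
      amplitude = as.numeric(amplitude),
      phase = as.numeric(phase) %% (2 * pi)
    ),
    class = "harmonic_component"
  )
}

#' Default harmonic set for nearshore Hawaiian reef temperatures
#'
#' Annual cycle plus the principal sub-daily bands seen in reef logger
#' spectra: the diurnal heating cycle (24 h), the principal lunar
#' semidiurnal internal tide M2 (12.42 h), the solar semidiurnal S2
#' (12.0 h), and a 25.82 h band. Amplitudes reflect a nearshore seasonal
#' range of roughly 24-27.5 degC with the semidiurnal internal tide
#' dominating the high-frequency bands.
#'
#' @param annual,diurnal,m2,s2,diurnal_lunar Amplitudes (deg C) for the
#'   8766 h, 24 h, 12.42 h, 12.0 h and 25.82 h components.
#' @param phases Optional numeric vector of five phases (radians).
#' @return List of [harmonic_component()] objects.
#' @export
default_harmonics <- function(annual = 1.2, diurnal = 0.10, m2 = 0.15,
                              s2 = 0.05, diurnal_lunar = 0.04,
                              phases = c(pi, 0, 0, 0, 0)) {
  periods <- c(8766, 24, 12.42, 12.0, 25.82)
  amps <- c(annual, diurnal, m2, s2, diurnal_lunar)
  Map(harmonic_component, periods, amps, phases)
}

#' Configuration for one synthetic reef site
#'
#' Describes the "true" high-frequency temperature signal recorded by a
#' logger at one site/depth: a mean level, a set of harmonics (annual,
#' diurnal, tidal), AR(1) red noise, white noise, and optional short
#' negative half-sine cooling pulses emulating internal bores.
#'
#' @param site_id Site identifier (unique within a site set).
#' @param lat,lon Decimal degrees.
#' @param depth_m Deployment depth, metres in (0, 30].
#' @param mean_temp Mean temperature, deg C.
#' @param harmonics List of [harmonic_component()].
#' @param noise_sd White noise standard deviation, deg C.
#' @param rednoise_sd Marginal (stationary) standard deviation of the AR(1)
#'   red-noise component, deg C.
#' @param rednoise_rho AR(1) coefficient at the observation cadence, in \[0, 1).
#' @param sample_interval_min Sampling cadence in minutes: 5 or 30.
#' @param start,end UTC timestamps (coerced with [as.POSIXct()]); `end > start`.
#' @param island Optional island label.
#' @param distance_to_shore_m Optional distance to shore, metres.
#' @param bore_rate_per_day Expected number of internal-bore cooling pulses
#'   per day (0 disables them, the default).
#' @param bore_amplitude Peak cooling of a pulse, deg C (positive number,
#'   subtracted from the signal).
#' @param bore_duration_h Pulse duration, hours.
#' @return A `synthetic_site_config` list.
#' @export
synthetic_site_config <- function(site_id, lat = 21.3, lon = -157.9,
                                  depth_m = 15, mean_temp = 25.5,
                                  harmonics = default_harmonics(),
                                  noise_sd = 0.05,
                                  rednoise_sd = 0.30, rednoise_rho = 0.98,
                                  sample_interval_min = 5,
                                  start = "2013-01-01 00:00:00",
                                  end = "2013-12-31 21:00:00",
                                  island = "Oahu",
                                  distance_to_shore_m = 500,
                                  bore_rate_per_day = 0,
                                  bore_amplitude = 1.0,
                                  bore_duration_h = 2) {
  start <- utc_time(start)
  end <- utc_time(end)
  if (!sample_interval_min %in% c(5, 30)) {
    stop("`sample_interval_min` must be 5 or 30")
  }
  if (end <= start) stop("degenerate time range: `end` must be after `start`")
  if (noise_sd < 0 || rednoise_sd < 0) stop("noise standard deviations must be >= 0")
  if (rednoise_rho < 0 || rednoise_rho >= 1) stop("`rednoise_rho` must be in [0, 1)")
  if (depth_m <= 0 || depth_m > 30) stop("`depth_m` must be in (0, 30]")
  for (h in harmonics) {
    if (!inherits(h, "harmonic_component")) {
      stop("`harmonics` must be a list of harmonic_component objects")
    }
  }
  structure(
    list(
      site_id = as.character(site_id), lat = lat, lon = lon,
      depth_m = depth_m, mean_temp = mean_temp, harmonics = harmonics,
      noise_sd = noise_sd, rednoise_sd = rednoise_sd,
      rednoise_rho = rednoise_rho,
      sample_interval_min = sample_interval_min,
      start = start, end = end, island = island,
      distance_to_shore_m = distance_to_shore_m,
      bore_rate_per_day = bore_rate_per_day,
      bore_amplitude = bore_amplitude,
      bore_duration_h = bore_duration_h
    ),
    class = "synthetic_site_config"
  )
}

#' Injectable model-error configuration
#'
#' Parameterizes how a 3-hourly model snapshot series is degraded relative
#' to the underlying truth: a constant bias, a seasonally varying bias, a
#' variance attenuation of high-frequency harmonics (emulating a model that
#' under-resolves sub-daily bands), and additional white noise.
#'
#' @param constant_bias Constant additive bias, deg C (positive = model warm).
#' @param seasonal_bias_amp Amplitude of a day-of-year cosine bias, deg C.
#' @param seasonal_bias_phase Phase of the seasonal bias, radians.
#' @param hf_attenuation Multiplicative factor in \[0, 1\] applied to the
#'   amplitude of harmonics with period below `attenuation_cutoff_hours`
#'   (1 = no attenuation).
#' @param attenuation_cutoff_hours Period cutoff, hours.
#' @param extra_noise_sd Additional model white noise, deg C.
#' @param snapshot_interval_hours Snapshot interval, hours (default 3).
#' @return A `model_error_config` list.
#' @export
model_error_config <- function(constant_bias = 0,
                               seasonal_bias_amp = 0, seasonal_bias_phase = 0,
                               hf_attenuation = 1,
                               attenuation_cutoff_hours = 30,
                               extra_noise_sd = 0,
                               snapshot_interval_hours = 3) {
  if (hf_attenuation < 0 || hf_attenuation > 1) {
    stop("`hf_attenuation` must be in [0, 1]")
  }
  if (snapshot_interval_hours <= 0) stop("`snapshot_interval_hours` must be > 0")
  if (extra_noise_sd < 0) stop("`extra_noise_sd` must be >= 0")
  structure(
    list(
      constant_bias = constant_bias,
      seasonal_bias_amp = seasonal_bias_amp,
      seasonal_bias_phase = seasonal_bias_phase,
      hf_attenuation = hf_attenuation,
      attenuation_cutoff_hours = attenuation_cutoff_hours,
      extra_noise_sd = extra_noise_sd,
      snapshot_interval_hours = snapshot_interval_hours
    ),
    class = "model_error_config"
  )
}

harmonic_sum <- function(t_hours, harmonics, attenuation = 1, cutoff = Inf) {
  out <- numeric(length(t_hours))
  for (h in harmonics) {
    a <- if (h$period_hours < cutoff) h$amplitude * attenuation else h$amplitude
    out <- out + a * cos(2 * pi * t_hours / h$period_hours + h$phase)
  }
  out
}

#' Generate a synthetic "true" (logger) temperature series
#'
#' Produces the high-frequency truth signal at the configured cadence:
#' `mean_temp` plus the harmonic sum plus AR(1) red noise plus white noise,
#' minus any internal-bore cooling pulses. Harmonic phases are anchored to
#' absolute time (hours since the Unix epoch) so co-located series generated
#' separately share phase. Deterministic given `(config, seed)`.
#'
#' @param config A [synthetic_site_config()].
#' @param seed Integer RNG seed.
#' @return A [temperature_series()] with `source = "observed"`. The series
#'   carries its generating components (config and realized non-harmonic
#'   signal) so that [degrade_to_model()] can attenuate harmonics exactly.
#' @export
generate_true_series <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_site_config"))
  if (missing(seed)) stop("`seed` is required")
  time <- seq(config$start, config$end, by = config$sample_interval_min * 60)
  n <- length(time)
  if (n < 2L) stop("degenerate time range: fewer than 2 samples")
  t_hours <- as.numeric(time) / 3600

  deterministic <- config$mean_temp + harmonic_sum(t_hours, config$harmonics)

  set.seed(seed)
  nonharmonic <- numeric(n)
  if (config$rednoise_sd > 0) {
    innov_sd <- config$rednoise_sd * sqrt(1 - config$rednoise_rho^2)
    init <- stats::rnorm(1, 0, config$rednoise_sd)
    nonharmonic <- nonharmonic + as.numeric(stats::filter(
      stats::rnorm(n, 0, innov_sd), config$rednoise_rho,
      method = "recursive", init = init
    ))
  }
  if (config$noise_sd > 0) {
    nonharmonic <- nonharmonic + stats::rnorm(n, 0, config$noise_sd)
  }
  if (config$bore_rate_per_day > 0) {
    span_days <- as.numeric(difftime(config$end, config$start, units = "days"))
    n_bores <- stats::rpois(1, config$bore_rate_per_day * span_days)
    if (n_bores > 0) {
      starts <- sort(stats::runif(n_bores, min(t_hours), max(t_hours)))
      for (s in starts) {
        inside <- t_hours >= s & t_hours <= s + config$bore_duration_h
        nonharmonic[inside] <- nonharmonic[inside] -
          config$bore_amplitude * sin(pi * (t_hours[inside] - s) / config$bore_duration_h)
      }
    }
  }

  out <- temperature_series(
    site_id = config$site_id, time = time, temp = deterministic + nonharmonic,
    depth_m = config$depth_m, lat = config$lat, lon = config$lon,
    source = "observed", cadence_min = config$sample_interval_min,
    island = config$island, distance_to_shore_m = config$distance_to_shore_m
  )
  out$sim <- list(config = config, nonharmonic = nonharmonic)
  out
}

#' Degrade a synthetic truth series into a 3-hourly model snapshot series
#'
#' Subsamples the truth instantaneously (snapshots, not window averages) on
#' the model's 3-hourly UTC grid, attenuating high-frequency harmonics and
#' adding constant bias, seasonal (day-of-year) bias and extra noise per the
#' error configuration. With a zero-error configuration the result equals
#' the truth at the snapshot timestamps exactly.
#'
#' Only accepts series produced by [generate_true_series()], which carry
#' their harmonic decomposition: attenuation rescales the harmonic
#' amplitudes themselves rather than filtering the realized signal.
#'
#' @param truth A series from [generate_true_series()].
#' @param err A [model_error_config()].
#' @param seed Integer seed for the extra model noise.
#' @return A [temperature_series()] with `source = "model"` at 3-hourly cadence.
#' @export
degrade_to_model <- function(truth, err = model_error_config(), seed = 1) {
  stopifnot(inherits(truth, "temperature_series"))
  if (is.null(truth$sim)) {
    stop("`truth` must carry its generating components (use generate_true_series())")
  }
  stopifnot(inherits(err, "model_error_config"))
  cfg <- truth$sim$config
  step_s <- err$snapshot_interval_hours * 3600
  if ((step_s %% (cfg$sample_interval_min * 60)) != 0) {
    stop("truth cadence must divide the snapshot interval")
  }
  secs <- as.numeric(truth$time)
  idx <- which(secs %% step_s == 0)
  if (length(idx) == 0L) stop("truth series too short for one snapshot")

  t_hours <- secs[idx] / 3600
  deterministic <- cfg$mean_temp + harmonic_sum(
    t_hours, cfg$harmonics,
    attenuation = err$hf_attenuation, cutoff = err$attenuation_cutoff_hours
  )
  vals <- deterministic + truth$sim$nonharmonic[idx] + err$constant_bias
  if (err$seasonal_bias_amp != 0) {
    doy <- day_of_year_frac(truth$time[idx])
    vals <- vals + err$seasonal_bias_amp *
      cos(2 * pi * doy / 365.25 + err$seasonal_bias_phase)
  }
  if (err$extra_noise_sd > 0) {
    set.seed(seed)
    vals <- vals + stats::rnorm(length(vals), 0, err$extra_noise_sd)
  }

  temperature_series(
    site_id = truth$site_id, time = truth$time[idx], temp = vals,
    depth_m = truth$depth_m, lat = truth$lat, lon = truth$lon,
    source = "model", cadence_min = err$snapshot_interval_hours * 60,
    island = truth$island, distance_to_shore_m = truth$distance_to_shore_m
  )
}

#' Build a default multi-site synthetic site set
#'
#' Lays out `n_sites` loggers across four island groups around the Main
#' Hawaiian Islands at nominal depths 5/15/25 m with varying distance to
#' shore, mirroring the scale of a regional monitoring array.
#'
#' @param n_sites Number of sites (default 25).
#' @param start,end Common deployment window (UTC).
#' @param sample_interval_min Logger cadence (5 or 30 min).
#' @param ... Further arguments passed to [synthetic_site_config()] for every
#'   site (e.g. `noise_sd`, `harmonics`).
#' @return List of [synthetic_site_config()] objects.
#' @export
synthetic_site_set <- function(n_sites = 25,
                               start = "2013-01-01 00:00:00",
                               end = "2013-12-31 21:00:00",
                               sample_interval_min = 5, ...) {
  if (n_sites < 1) stop("need at least one site")
  islands <- c("Hawaii", "Maui", "Oahu", "Kauai")
  depths <- c(5, 15, 25)
  lat0 <- c(19.6, 20.8, 21.3, 22.1)
  lon0 <- c(-155.5, -156.3, -157.9, -159.5)
  lapply(seq_len(n_sites), function(i) {
    isl <- ((i - 1L) %% 4L) + 1L
    synthetic_site_config(
      site_id = sprintf("SYN%02d", i),
      lat = lat0[isl] + 0.03 * ((i - 1L) %/% 4L),
      lon = lon0[isl] - 0.02 * ((i - 1L) %/% 4L),
      depth_m = depths[((i - 1L) %% 3L) + 1L],
      island = islands[isl],
      distance_to_shore_m = 100 + 150 * ((i - 1L) %% 8L),
      start = start, end = end,
      sample_interval_min = sample_interval_min, ...
    )
  })
}

#' Generate a paired observation/model archive for a set of sites
#'
#' For each site, generates the truth series (the synthetic logger record)
#' and its degraded 3-hourly model counterpart. Per-site seeds are derived
#' deterministically from the master seed.
#'
#' @param site_configs List of [synthetic_site_config()] with unique site ids.
#' @param err A [model_error_config()] applied to every site.
#' @param seed Master integer seed.
#' @return A list with elements `obs` and `model`, each a named list of
#'   [temperature_series()] keyed by site id.
#' @export
make_paired_dataset <- function(site_configs, err = model_error_config(), seed = 1) {
  if (length(site_configs) == 0L) stop("`site_configs` must contain at least one site")
  ids <- vapply(site_configs, function(cfg) cfg$site_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate site_id in `site_configs`: ", ids[duplicated(ids)][1])
  }
  obs <- vector("list", length(ids))
  mod <- vector("list", length(ids))
  for (i in seq_along(site_configs)) {
    sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
    obs[[i]] <- generate_true_series(site_configs[[i]], seed = sub_seed)
    mod[[i]] <- degrade_to_model(obs[[i]], err, seed = sub_seed + 104729L)
  }
  names(obs) <- ids
  names(mod) <- ids
  list(obs = obs, model = mod)
}

#' Write temperature series to the observation CSV layout
#'
#' Writes one row per sample with columns `site_id, island, latitude,
#' longitude, depth, distance_to_shore, time, temperature` — the same
#' tabledap-style layout [read_obs_csv()] ingests.
#'
#' @param series_list A [temperature_series()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_obs_csv <- function(series_list, path) {
  if (inherits(series_list, "temperature_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    data.frame(
      site_id = s$site_id, island = s$island,
      latitude = s$lat, longitude = s$lon, depth = s$depth_m,
      distance_to_shore = s$distance_to_shore_m,
      time = format(s$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      temperature = s$temp
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
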