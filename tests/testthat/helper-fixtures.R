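# Small site configurations used across the suite. Kept deliberately short
# so individual tests stay fast; the acceptance tests build the full-scale
# archives themselves.

quiet_config <- function(..., site_id = "Q1") {
  # no harmonics, no noise: a constant series at mean_temp
  synthetic_site_config(
    site_id = site_id, harmonics = list(),
    noise_sd = 0, rednoise_sd = 0, ...
  )
}

one_harmonic_config <- function(amplitude = 0.5, period_hours = 12.42,
                                phase = 0, site_id = "H1", ...) {
  synthetic_site_config(
    site_id = site_id,
    harmonics = list(harmonic_component(period_hours, amplitude, phase)),
    noise_sd = 0, rednoise_sd = 0, ...
  )
}

# random paired dataset (no structure) for oracle-equivalence checks
random_pairs <- function(n, seed = 1, obs_mean = 25, sd = 1, bias = 0, model_sd = 1) {
  set.seed(seed)
  paired_dataset(data.frame(
    site_id = "R1",
    time = as.POSIXct("2013-06-01", tz = "UTC") + 10800 * seq_len(n),
    obs = obs_mean + rnorm(n, 0, sd),
    model = obs_mean + bias + rnorm(n, 0, model_sd)
  ))
}

# independent great-circle distance (spherical law of cosines), used as the
# oracle for nearest-cell selection
slc_distance <- function(lat1, lon1, lat2, lon2, R = 6378137) {
  to_rad <- pi / 180
  acos(pmin(1, sin(lat1 * to_rad) * sin(lat2 * to_rad) +
              cos(lat1 * to_rad) * cos(lat2 * to_rad) *
                cos((lon2 - lon1) * to_rad))) * R
}
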