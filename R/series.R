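#' Temperature series for one site and depth
#'
#' Lightweight container for a timestamped temperature record from a single
#' reef site/depth, either an in situ logger record (`source = "observed"`)
#' or an ocean-model extraction (`source = "model"`). Timestamps are UTC and
#' strictly increasing; values are degrees Celsius.
#'
#' @param site_id Character site identifier.
#' @param time `POSIXct` timestamps (UTC), strictly increasing.
#' @param temp Numeric temperatures, deg C, same length as `time`.
#' @param depth_m Deployment depth in metres (positive).
#' @param lat,lon Decimal degrees; may be `NA` for purely synthetic work.
#' @param source `"observed"` or `"model"`.
#' @param cadence_min Nominal sampling interval in minutes; inferred from the
#'   median timestamp difference when `NULL`.
#' @param island Optional island/region label used for grouped skill tables.
#' @param distance_to_shore_m Optional distance to shore in metres.
#'
#' @return An object of class `temperature_series`: a list with elements
#'   `site_id`, `island`, `lat`, `lon`, `depth_m`, `distance_to_shore_m`,
#'   `source`, `cadence_min`, `time`, `temp`.
#' @export
temperature_series <- function(site_id, time, temp, depth_m,
                               lat = NA_real_, lon = NA_real_,
                               source = c("observed", "model"),
                               cadence_min = NULL,
                               island = NA_character_,
                               distance_to_shore_m = NA_real_) {
  source <- match.arg(source)
  if (!inherits(time, "POSIXct")) {
    stop("`time` must be POSIXct (UTC)")
  }
  if (length(time) != length(temp)) {
    stop("`time` and `temp` must have the same length")
  }
  if (length(time) == 0L) stop("empty series")
  dt <- diff(as.numeric(time))
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (!is.na(depth_m) && depth_m <= 0) stop("`depth_m` must be positive")
  bad <- sum(temp < 0 | temp > 40, na.rm = TRUE)
  if (bad > 0) {
    warning(sprintf("%d temperature value(s) outside the plausible 0-40 degC range", bad))
  }
  if (is.null(cadence_min)) {
    cadence_min <- if (length(dt)) stats::median(dt) / 60 else NA_real_
  }
  structure(
    list(
      site_id = as.character(site_id), island = island,
      lat = lat, lon = lon, depth_m = depth_m,
      distance_to_shore_m = distance_to_shore_m,
      source = source, cadence_min = cadence_min,
      time = time, temp = as.numeric(temp)
    ),
    class = "temperature_series"
  )
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf(
    "<temperature_series> site %s (%s), depth %.1f m, %d samples @ %.0f min\n  %s .. %s, mean %.2f degC\n",
    x$site_id, x$source, x$depth_m, length(x$temp), x$cadence_min,
    format(x$time[1], tz = "UTC"), format(x$time[length(x$time)], tz = "UTC"),
    mean(x$temp, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
length.temperature_series <- function(x) length(x$temp)

# calendar quarter season label (JFM / AMJ / JAS / OND)
season_label <- function(time) {
  m <- as.POSIXlt(time, tz = "UTC")$mon + 1L
  c("JFM", "AMJ", "JAS", "OND")[(m - 1L) %/% 3L + 1L]
}

# integer day of year, 1..366
day_of_year <- function(time) as.POSIXlt(time, tz = "UTC")$yday + 1L

# fractional day of year (used for smoothly varying seasonal error terms)
day_of_year_frac <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$yday + 1 + (lt$hour + (lt$min + lt$sec / 60) / 60) / 24
}

utc_time <- function(x) as.POSIXct(x, tz = "UTC")
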