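parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- sub("Z$", "", sub("T", " ", as.character(x)))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (anyNA(out)) stop("unparseable timestamp(s), e.g. ", x[which(is.na(out))[1]])
  out
}

#' Read logger observations from a tabledap-style CSV
#'
#' Expects one row per sample with at least the columns `site_id`,
#' `latitude`, `longitude`, `depth`, `time` (ISO-8601, UTC) and
#' `temperature`. Optional `island` and `distance_to_shore` columns are
#' carried into the series metadata. Rows with missing temperature are
#' dropped (with a message giving the count); non-monotone timestamps are
#' sorted with a warning.
#'
#' @param path CSV file path.
#' @return A named list of [temperature_series()], one per `(site_id, depth)`
#'   combination, keyed `"<site_id>@<depth>m"` (or just the site id when a
#'   site has a single depth).
#' @export
read_obs_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site_id", "latitude", "longitude", "depth", "time", "temperature")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n_na <- sum(is.na(df$temperature) | df$temperature == "")
  if (n_na > 0) {
    message(n_na, " row(s) with missing temperature dropped")
    df <- df[!(is.na(df$temperature) | df$temperature == ""), , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no usable rows in ", path)
  df$time <- parse_utc(df$time)

  key <- paste(df$site_id, df$depth, sep = "\r")
  groups <- split(df, factor(key, levels = unique(key)))
  multi_depth <- vapply(groups, function(g) g$site_id[1], character(1))
  multi_depth <- multi_depth[duplicated(multi_depth)]

  out <- lapply(groups, function(g) {
    if (is.unsorted(as.numeric(g$time), strictly = TRUE)) {
      warning("non-monotone timestamps for site ", g$site_id[1], "; sorting")
      g <- g[order(g$time), , drop = FALSE]
    }
    temperature_series(
      site_id = g$site_id[1], time = g$time, temp = as.numeric(g$temperature),
      depth_m = g$depth[1], lat = g$latitude[1], lon = g$longitude[1],
      source = "observed",
      island = if ("island" %in% names(g)) g$island[1] else NA_character_,
      distance_to_shore_m = if ("distance_to_shore" %in% names(g)) {
        g$distance_to_shore[1]
      } else NA_real_
    )
  })
  names(out) <- vapply(groups, function(g) {
    if (g$site_id[1] %in% multi_depth) {
      sprintf("%s@%gm", g$site_id[1], g$depth[1])
    } else g$site_id[1]
  }, character(1))
  out
}

#' Extract a model series at the grid cell nearest a site
#'
#' Reads a griddap-style long-format CSV with columns `time`, `depth`,
#' `latitude`, `longitude`, `temperature` (one row per grid cell per
#' snapshot) and returns the 3-hourly series of the requested depth stratum
#' at the grid cell nearest `(lat, lon)` by great-circle distance. Distance
#' ties resolve to the cell appearing first in the file.
#'
#' @param path Long-format CSV path.
#' @param lat,lon Target location, decimal degrees.
#' @param stratum_m Depth stratum to extract (must exist exactly in `depth`).
#' @param site_id Site id to stamp on the returned series.
#' @return A [temperature_series()] with `source = "model"`.
#' @export
read_model_series <- function(path, lat, lon, stratum_m, site_id = "model") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time", "depth", "latitude", "longitude", "temperature")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  strata <- sort(unique(df$depth))
  if (!stratum_m %in% strata) {
    stop("stratum ", stratum_m, " m not in file; available strata: ",
         paste(strata, collapse = ", "), " m")
  }
  df <- df[df$depth == stratum_m, , drop = FALSE]

  cell_key <- paste(df$latitude, df$longitude, sep = "\r")
  cells_idx <- !duplicated(cell_key)
  cells <- df[cells_idx, c("latitude", "longitude")]
  dlat <- max(diff(sort(unique(cells$latitude))), 0.05)
  dlon <- max(diff(sort(unique(cells$longitude))), 0.05)
  if (lat < min(cells$latitude) - dlat || lat > max(cells$latitude) + dlat ||
      lon < min(cells$longitude) - dlon || lon > max(cells$longitude) + dlon) {
    stop("requested point (", lat, ", ", lon, ") lies outside the grid domain")
  }
  d <- geosphere::distHaversine(cbind(lon, lat), cbind(cells$longitude, cells$latitude))
  nearest <- which.min(d) # ties -> first (lower index)
  sel <- cell_key == cell_key[cells_idx][nearest]
  g <- df[sel, , drop = FALSE]
  g$time <- parse_utc(g$time)
  g <- g[order(g$time), , drop = FALSE]
  temperature_series(
    site_id = site_id, time = g$time, temp = as.numeric(g$temperature),
    depth_m = stratum_m, lat = g$latitude[1], lon = g$longitude[1],
    source = "model"
  )
}

#' Match a logger deployment depth to the nearest model stratum
#'
#' Returns the stratum minimizing the absolute depth difference; exact ties
#' resolve to the shallower stratum.
#'
#' @param obs_depth_m Logger depth, metres.
#' @param strata Numeric vector of available model strata (metres).
#' @return The selected stratum (metres).
#' @export
match_depth <- function(obs_depth_m, strata = c(5, 10, 20, 30)) {
  if (length(strata) == 0L) stop("`strata` must be non-empty")
  d <- abs(strata - obs_depth_m)
  min(strata[d == min(d)])
}

#' Pair a logger series with a 3-hourly model snapshot series
#'
#' For every model snapshot, the observation is the mean of logger samples
#' in a window centred on the snapshot time: +/- 10 min for a 5-min cadence
#' and +/- 1 h for a 30-min cadence (both inclusive of the endpoints, so a
#' complete window holds 5 measurements). Matchups outside the overlap of
#' the two series, or with fewer than `min_window_n` logger samples in the
#' window, are not emitted; the per-window sample count is recorded.
#'
#' @param obs Observed [temperature_series()] at 5- or 30-min cadence.
#' @param model Model [temperature_series()] at 3-hourly cadence.
#' @param min_window_n Minimum logger samples per window (default 3; set to
#'   1 to keep every non-empty window).
#' @return A `paired_dataset`: a data frame with one row per matchup and
#'   columns `site_id, island, lat, lon, depth_m, distance_to_shore_m, time,
#'   obs, model, n_obs_in_window, year, doy, season`.
#' @export
pair_series <- function(obs, model, min_window_n = 3) {
  stopifnot(inherits(obs, "temperature_series"), inherits(model, "temperature_series"))
  if (obs$site_id != model$site_id) {
    stop("series are from different sites: ", obs$site_id, " vs ", model$site_id)
  }
  cad <- round(obs$cadence_min)
  if (!cad %in% c(5L, 30L)) {
    stop("unsupported observation cadence ", obs$cadence_min,
         " min (must be 5 or 30)")
  }
  if (abs(model$cadence_min - 180) > 1) {
    stop("model series must be 3-hourly (cadence ", model$cadence_min, " min)")
  }
  half_window_s <- if (cad == 5L) 600 else 3600

  ot <- as.numeric(obs$time)
  mt <- as.numeric(model$time)
  hi <- findInterval(mt + half_window_s + 0.5, ot)
  lo <- findInterval(mt - half_window_s - 0.5, ot)
  n_in <- hi - lo
  cs <- c(0, cumsum(obs$temp))
  obs_mean <- (cs[hi + 1] - cs[lo + 1]) / n_in

  keep <- n_in >= max(1L, min_window_n) &
    mt >= ot[1] & mt <= ot[length(ot)] # never emit outside the series overlap
  tm <- model$time[keep]
  out <- data.frame(
    site_id = obs$site_id, island = obs$island,
    lat = obs$lat, lon = obs$lon, depth_m = obs$depth_m,
    distance_to_shore_m = obs$distance_to_shore_m,
    time = tm, obs = obs_mean[keep], model = model$temp[keep],
    n_obs_in_window = n_in[keep],
    year = as.POSIXlt(tm, tz = "UTC")$year + 1900L,
    doy = day_of_year(tm),
    season = season_label(tm),
    stringsAsFactors = FALSE
  )
  as_paired_dataset(out)
}

#' Construct a paired dataset from matchup columns
#'
#' Builds the `paired_dataset` data frame that all statistics consume from
#' already-matched columns. [pair_series()] is the usual producer; this
#' constructor serves programmatic construction (e.g. simulation studies).
#' `year`, `doy` and `season` are derived from `time` when absent.
#'
#' @param df A data frame with at least `site_id`, `time` (`POSIXct`, UTC),
#'   `obs`, `model`; optional `island`, `lat`, `lon`, `depth_m`,
#'   `distance_to_shore_m`, `n_obs_in_window`.
#' @return A `paired_dataset`.
#' @export
paired_dataset <- function(df) {
  need <- c("site_id", "time", "obs", "model")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("island")) if (is.null(df[[col]])) df[[col]] <- NA_character_
  for (col in c("lat", "lon", "depth_m", "distance_to_shore_m")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  if (is.null(df$n_obs_in_window)) df$n_obs_in_window <- 1L
  if (is.null(df$year)) df$year <- as.POSIXlt(df$time, tz = "UTC")$year + 1900L
  if (is.null(df$doy)) df$doy <- day_of_year(df$time)
  if (is.null(df$season)) df$season <- season_label(df$time)
  as_paired_dataset(as.data.frame(df))
}

as_paired_dataset <- function(df) {
  if (anyDuplicated(df[c("site_id", "time")])) {
    stop("duplicate (site_id, time) keys in paired dataset")
  }
  class(df) <- c("paired_dataset", "data.frame")
  df
}

#' Pair a whole archive of observation and model series
#'
#' Convenience wrapper running [pair_series()] over matching site ids (e.g.
#' the output of [make_paired_dataset()]) and row-binding the results.
#'
#' @param obs_list,model_list Named lists of [temperature_series()] sharing
#'   site ids.
#' @param min_window_n Passed to [pair_series()].
#' @return A `paired_dataset` covering all sites.
#' @export
pair_archive <- function(obs_list, model_list, min_window_n = 3) {
  ids <- vapply(obs_list, function(s) s$site_id, character(1))
  mids <- vapply(model_list, function(s) s$site_id, character(1))
  if (!setequal(ids, mids)) stop("observation and model site ids do not match")
  pieces <- lapply(seq_along(obs_list), function(i) {
    m <- model_list[[match(ids[i], mids)]]
    pair_series(obs_list[[i]], m, min_window_n = min_window_n)
  })
  as_paired_dataset(do.call(rbind, lapply(pieces, as.data.frame)))
}

#' Drop matchups from the model's spin-up period
#'
#' Removes all samples earlier than the cutoff (default 2011-01-01 00:00 UTC,
#' the point at which the reanalysis assimilation is equilibrated). The raw
#' overall comparison typically uses the full series; the Taylor-diagram and
#' bias-GAM stages apply this exclusion.
#'
#' @param ds A `paired_dataset`.
#' @param cutoff UTC instant; samples strictly before it are removed.
#' @return The filtered `paired_dataset`.
#' @export
exclude_spinup <- function(ds, cutoff = "2011-01-01 00:00:00") {
  cutoff <- utc_time(cutoff)
  out <- ds[ds$time >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  as_paired_dataset(as.data.frame(out))
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf(
    "<paired_dataset> %d matchups, %d site(s), %s .. %s\n",
    nrow(x), length(unique(x$site_id)),
    format(min(x$time), tz = "UTC"), format(max(x$time), tz = "UTC")
  ))
  invisible(x)
}
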