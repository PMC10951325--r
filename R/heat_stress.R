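# Accept either a temperature_series or a plain (time, temp) data frame.
as_time_temp <- function(x) {
  if (inherits(x, "temperature_series")) {
    data.frame(time = x$time, temp = x$temp)
  } else if (is.data.frame(x) && all(c("time", "temp") %in% names(x))) {
    x[c("time", "temp")]
  } else {
    stop("expected a temperature_series or a data frame with `time` and `temp`")
  }
}

series_source <- function(x) {
  if (inherits(x, "temperature_series")) x$source else attr(x, "source") %||% NA_character_
}

#' Pool a paired dataset into one site-averaged series per source
#'
#' Averages the observed (windowed logger means) or model (snapshot) values
#' across sites at each 3-hourly timestamp, giving the regional series the
#' climatology/anomaly and spectral analyses consume.
#'
#' @param ds A `paired_dataset`.
#' @param source `"observed"` or `"model"`.
#' @return A data frame `time`, `temp` with a `source` attribute.
#' @export
pooled_series <- function(ds, source = c("observed", "model")) {
  source <- match.arg(source)
  v <- if (source == "observed") ds$obs else ds$model
  agg <- tapply(v, as.numeric(ds$time), mean)
  out <- data.frame(
    time = utc_time(as.POSIXct(as.numeric(names(agg)), origin = "1970-01-01", tz = "UTC")),
    temp = as.numeric(agg)
  )
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- source
  out
}

#' Monthly climatological temperatures
#'
#' Long-term mean for each calendar month over the baseline years, computed
#' within one source (observed and model datasets each get their own
#' climatology).
#'
#' @param series A [temperature_series()] or `(time, temp)` data frame.
#' @param baseline_years Years included in the baseline (default 2010:2017).
#' @return A `climatology_table` data frame: `month` (1-12), `climatology`
#'   (deg C), with `source` and `baseline` attributes.
#' @export
monthly_climatology <- function(series, baseline_years = 2010:2017) {
  tt <- as_time_temp(series)
  lt <- as.POSIXlt(tt$time, tz = "UTC")
  keep <- (lt$year + 1900L) %in% baseline_years
  if (!any(keep)) stop("no samples fall inside the baseline years")
  mth <- lt$mon[keep] + 1L
  present <- sort(unique(mth))
  missing_m <- setdiff(1:12, present)
  if (length(missing_m)) {
    stop("no baseline samples in month(s): ", paste(missing_m, collapse = ", "))
  }
  clim <- as.numeric(tapply(tt$temp[keep], mth, mean))
  out <- data.frame(month = 1:12, climatology = clim)
  attr(out, "source") <- series_source(series)
  attr(out, "baseline") <- range(baseline_years)
  class(out) <- c("climatology_table", "data.frame")
  out
}

#' Monthly temperature anomalies from a climatology
#'
#' One anomaly per (year, month) present in the series: the monthly mean
#' minus the climatological mean for that calendar month. The climatology
#' must come from the same source as the series.
#'
#' @param series A [temperature_series()] or `(time, temp)` data frame.
#' @param clim A [monthly_climatology()] table from the same source.
#' @return A data frame `year`, `month`, `monthly_mean`, `anomaly` (deg C),
#'   `n_samples`.
#' @export
monthly_anomalies <- function(series, clim) {
  stopifnot(inherits(clim, "climatology_table"))
  src_s <- series_source(series)
  src_c <- attr(clim, "source")
  if (!is.na(src_s) && !is.na(src_c) && src_s != src_c) {
    stop("source mismatch: series is `", src_s, "` but climatology is `", src_c, "`")
  }
  tt <- as_time_temp(series)
  lt <- as.POSIXlt(tt$time, tz = "UTC")
  key <- data.frame(year = lt$year + 1900L, month = lt$mon + 1L)
  agg <- stats::aggregate(tt$temp, key, mean)
  cnt <- stats::aggregate(tt$temp, key, length)
  out <- data.frame(
    year = agg$year, month = agg$month, monthly_mean = agg$x,
    anomaly = agg$x - clim$climatology[agg$month],
    n_samples = cnt$x
  )
  out[order(out$year, out$month), , drop = FALSE]
}

#' Daily mean temperatures from a paired dataset
#'
#' Aggregates one source of a paired dataset to calendar-UTC-day means,
#' either pooled across sites (default) or per site.
#'
#' @param ds A `paired_dataset`.
#' @param source `"observed"` or `"model"`.
#' @param per_site Keep sites separate? Default `FALSE` (pooled).
#' @return A data frame `date`, `temp` (plus `site_id` when `per_site`).
#' @export
daily_means <- function(ds, source = c("observed", "model"), per_site = FALSE) {
  source <- match.arg(source)
  v <- if (source == "observed") ds$obs else ds$model
  date <- as.Date(ds$time, tz = "UTC")
  if (per_site) {
    agg <- stats::aggregate(v, list(site_id = ds$site_id, date = date), mean)
    names(agg)[3] <- "temp"
    agg[order(agg$site_id, agg$date), , drop = FALSE]
  } else {
    agg <- stats::aggregate(v, list(date = date), mean)
    names(agg)[2] <- "temp"
    agg[order(agg$date), , drop = FALSE]
  }
}

#' Seasonally detrended daily temperatures
#'
#' Fits daily mean temperature as a cyclic cubic spline in day of year
#' (cycle closed between day 1 and day 366, REML smoothing) and returns the
#' residuals — daily temperatures with the seasonal trend removed. Short
#' cold or warm excursions from the seasonal cycle stand out as large
#' negative or positive residuals.
#'
#' @param daily A data frame with `date` (`Date`) and `temp` (deg C).
#' @param k Basis dimension of the cyclic spline (default 20).
#' @return A data frame `date`, `temp`, `fitted`, `residual`, with the fit's
#'   r-squared as attribute `r_squared`.
#' @export
seasonal_detrend <- function(daily, k = 20) {
  if (!all(c("date", "temp") %in% names(daily))) {
    stop("`daily` must have `date` and `temp` columns")
  }
  doy <- as.POSIXlt(daily$date)$yday + 1
  if (length(unique(doy)) < 180L) {
    stop("need at least 180 distinct days of year to identify the seasonal cycle")
  }
  d <- data.frame(temp = daily$temp, doy = doy)
  k <- min(k, length(unique(doy)) - 1L)
  fit <- mgcv::gam(temp ~ s(doy, bs = "cc", k = k), data = d,
                   method = "REML", knots = list(doy = c(1, 366)))
  fitted <- as.numeric(stats::fitted(fit))
  out <- data.frame(date = daily$date, temp = daily$temp, fitted = fitted,
                    residual = daily$temp - fitted)
  attr(out, "r_squared") <- as.numeric(summary(fit)$r.sq)
  out
}

#' 14-day temperature means and coefficients of variation
#'
#' Splits a series into consecutive, non-overlapping 14-day blocks anchored
#' at the series' start date and reports each block's mean and CV
#' (sd / mean, computed on deg C). A trailing partial block is dropped when
#' it covers fewer than 7 distinct days.
#'
#' @param series A [temperature_series()] or `(time, temp)` data frame.
#' @param site_id Site label for the output (taken from the series if absent).
#' @return A data frame `site_id`, `window_start` (`Date`), `mean`, `sd`,
#'   `cv`, `n_samples`, `n_days`.
#' @export
biweekly_metrics <- function(series, site_id = NULL) {
  tt <- as_time_temp(series)
  if (nrow(tt) == 0L) stop("empty series")
  if (is.null(site_id)) {
    site_id <- if (inherits(series, "temperature_series")) series$site_id else "site"
  }
  date <- as.Date(tt$time, tz = "UTC")
  start <- min(date)
  block <- as.integer(floor(as.numeric(date - start) / 14))
  out <- do.call(rbind, lapply(split(seq_len(nrow(tt)), block), function(i) {
    v <- tt$temp[i]
    data.frame(
      site_id = site_id,
      window_start = start + 14 * block[i[1]],
      mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else 0,
      n_samples = length(v),
      n_days = length(unique(date[i]))
    )
  }))
  out <- out[order(out$window_start), , drop = FALSE]
  # trailing partial block with under 7 days of data is dropped
  last <- which.max(as.numeric(out$window_start))
  if (out$n_days[last] < 7 && nrow(out) > 1) out <- out[-last, , drop = FALSE]
  out$cv <- out$sd / out$mean
  rownames(out) <- NULL
  out[c("site_id", "window_start", "mean", "sd", "cv", "n_samples", "n_days")]
}

#' Per-site biweekly metrics from a paired dataset
#'
#' Runs [biweekly_metrics()] on one source of every site in a paired
#' dataset. Observed and model windows share timestamps, so the windows are
#' directly comparable site by site.
#'
#' @param ds A `paired_dataset`.
#' @param source `"observed"` or `"model"`.
#' @param months Optional month filter (e.g. `7:10` for the peak-bleaching
#'   Jul-Oct subset) applied before windowing.
#' @return A data frame as from [biweekly_metrics()], all sites stacked.
#' @export
biweekly_from_pairs <- function(ds, source = c("observed", "model"), months = NULL) {
  source <- match.arg(source)
  if (!is.null(months)) {
    m <- as.POSIXlt(ds$time, tz = "UTC")$mon + 1L
    ds <- ds[m %in% months, , drop = FALSE]
    if (nrow(ds) == 0L) stop("no samples in the requested months")
  }
  v <- if (source == "observed") ds$obs else ds$model
  pieces <- lapply(split(seq_len(nrow(ds)), ds$site_id), function(i) {
    biweekly_metrics(data.frame(time = ds$time[i], temp = v[i]),
                     site_id = ds$site_id[i[1]])
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Compare a biweekly metric between model and observations
#'
#' Ordinary least-squares regression of the model metric on the observed
#' metric over windows matched by `(site_id, window_start)`. A slope below 1
#' with positive intercept near zero indicates the model under-represents
#' the metric's range.
#'
#' @param obs_windows,model_windows Outputs of [biweekly_metrics()] /
#'   [biweekly_from_pairs()] for the observed and model series.
#' @param metric `"biweekly_mean"` or `"biweekly_cv"`.
#' @return A `metric_comparison` list: `metric`, `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
compare_metric <- function(obs_windows, model_windows,
                           metric = c("biweekly_mean", "biweekly_cv")) {
  metric <- match.arg(metric)
  col <- if (metric == "biweekly_mean") "mean" else "cv"
  m <- merge(obs_windows[c("site_id", "window_start", col)],
             model_windows[c("site_id", "window_start", col)],
             by = c("site_id", "window_start"), suffixes = c("_obs", "_model"))
  if (nrow(m) < 3L) stop("need at least 3 matched windows")
  x <- m[[paste0(col, "_obs")]]
  y <- m[[paste0(col, "_model")]]
  if (stats::sd(x) == 0) stop("observed metric is constant: regression degenerate")
  fit <- stats::lm(y ~ x)
  structure(
    list(metric = metric,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         n = nrow(m)),
    class = "metric_comparison"
  )
}

#' @export
print.metric_comparison <- function(x, ...) {
  cat(sprintf(
    "<metric_comparison> %s: model = %.3f * obs + %.4f, r^2 = %.3f (n = %d)\n",
    x$metric, x$slope, x$intercept, x$r_squared, x$n
  ))
  invisible(x)
}
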