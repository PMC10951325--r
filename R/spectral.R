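#' Raw periodogram of a temperature series, variance-scaled
#'
#' Computes the one-sided periodogram of a regularly sampled series via the
#' FFT after mean removal. The frequency axis is converted to cycles per
#' hour by dividing the per-sample frequency by the sampling interval, and
#' the density is multiplied by two (one-sided folding) and scaled so the
#' area under the curve over frequency matches the series variance
#' (deg C^2 per cycle/hour).
#'
#' Gaps up to `max_gap_hours` are filled by linear interpolation (flagged in
#' the result); longer gaps split the series into segments whose spectra
#' are averaged, length-weighted, on the longest segment's frequency grid.
#'
#' @param series A [temperature_series()] or `(time, temp)` data frame at
#'   regular cadence.
#' @param max_gap_hours Longest gap filled by interpolation (default 24 h).
#' @param taper Proportion of the series split-cosine tapered at each end
#'   (default 0, no taper).
#' @return A `temp_spectrum` list: `frequency` (cycles/hour, strictly
#'   increasing up to Nyquist), `period_hours`, `density`, `spans`
#'   (empty until smoothed), `n`, `delta_hours`, `variance`, `interpolated`,
#'   `n_segments`, `detrended`.
#' @export
periodogram <- function(series, max_gap_hours = 24, taper = 0) {
  tt <- as_time_temp(series)
  n0 <- nrow(tt)
  if (n0 < 8L) stop("series too short for a periodogram")
  secs <- as.numeric(tt$time)
  dt <- diff(secs)
  step <- min(dt)
  if (step <= 0) stop("timestamps must be strictly increasing")
  if (any(abs(dt / step - round(dt / step)) > 1e-6)) {
    stop("irregular cadence: timestamps are not on a regular grid")
  }
  delta_hours <- step / 3600

  # regular grid over the full span; interpolate short gaps, split on long ones
  grid <- seq(secs[1], secs[n0], by = step)
  x <- rep(NA_real_, length(grid))
  x[round((secs - secs[1]) / step) + 1] <- tt$temp
  interpolated <- FALSE
  gap_runs <- rle(is.na(x))
  max_gap_steps <- floor(max_gap_hours * 3600 / step)
  if (anyNA(x)) {
    long_gap <- gap_runs$values & gap_runs$lengths > max_gap_steps
    if (any(gap_runs$values & !long_gap)) {
      x_f <- stats::approx(grid[!is.na(x)], x[!is.na(x)], xout = grid)$y
      # keep long gaps as NA so they still split the series below
      ends <- cumsum(gap_runs$lengths)
      starts <- ends - gap_runs$lengths + 1
      x <- x_f
      for (j in which(long_gap)) x[starts[j]:ends[j]] <- NA
      interpolated <- TRUE
    }
  }
  seg_id <- cumsum(c(TRUE, is.na(x[-length(x)]) & !is.na(x[-1])))
  seg_id[is.na(x)] <- NA
  segs <- split(x[!is.na(x)], seg_id[!is.na(x)])
  segs <- segs[vapply(segs, length, integer(1)) >= 8L]
  if (length(segs) == 0L) stop("no segment long enough for a periodogram")

  one_segment <- function(v) {
    n <- length(v)
    v <- v - mean(v)
    if (taper > 0) v <- stats::spec.taper(v, p = taper)
    X <- stats::fft(v)
    m <- n %/% 2L
    j <- seq_len(m)
    dens <- 2 * delta_hours * Mod(X[j + 1])^2 / n
    if (n %% 2L == 0L) dens[m] <- dens[m] / 2 # Nyquist is its own conjugate
    list(freq = j / (n * delta_hours), density = dens, n = n)
  }

  specs <- lapply(segs, one_segment)
  main <- specs[[which.max(vapply(specs, `[[`, integer(1), "n"))]]
  if (length(specs) == 1L) {
    freq <- main$freq
    density <- main$density
  } else {
    freq <- main$freq
    w <- vapply(specs, `[[`, integer(1), "n")
    dens_mat <- vapply(specs, function(s) {
      stats::approx(s$freq, s$density, xout = freq, rule = 2)$y
    }, numeric(length(freq)))
    density <- as.numeric(dens_mat %*% (w / sum(w)))
  }

  structure(
    list(frequency = freq, period_hours = 1 / freq, density = density,
         spans = integer(0), n = sum(vapply(specs, `[[`, integer(1), "n")),
         delta_hours = delta_hours,
         variance = stats::var(tt$temp),
         interpolated = interpolated, n_segments = length(specs),
         detrended = TRUE),
    class = "temp_spectrum"
  )
}

#' @export
print.temp_spectrum <- function(x, ...) {
  cat(sprintf(
    "<temp_spectrum> %d bins, %.1f h cadence, Nyquist %.4f cph, area %.4f degC^2%s\n",
    length(x$frequency), x$delta_hours, max(x$frequency), spectrum_area(x),
    if (length(x$spans)) paste0(", Daniell spans [", paste(x$spans, collapse = ","), "]") else ""
  ))
  invisible(x)
}

#' Area under a spectrum (trapezoid-free bin sum)
#'
#' Sum of density times the frequency bin width; approximately the series
#' variance for the variance-scaled periodogram.
#'
#' @param spec A `temp_spectrum`.
#' @return Scalar area, deg C^2.
#' @export
spectrum_area <- function(spec) {
  df <- spec$frequency[2] - spec$frequency[1]
  sum(spec$density) * df
}

modified_daniell_weights <- function(span) {
  m <- (span - 1L) / 2L
  if (m == 0L) return(1)
  c(1 / (4 * m), rep(1 / (2 * m), 2L * m - 1L), 1 / (4 * m))
}

#' Smooth a periodogram with (iterated) modified Daniell kernels
#'
#' Convolves the density with modified Daniell kernels (centered moving
#' averages with half-weight endpoints), one per entry of `spans`, applied
#' as a single composite kernel. Endpoints are handled by half-sample
#' reflection, which preserves the total area exactly.
#'
#' @param spec A `temp_spectrum`.
#' @param spans Odd positive integers; `c(9, 9)` by default. A span of 1 is
#'   the identity.
#' @return The smoothed `temp_spectrum` with `spans` recorded.
#' @export
smooth_daniell <- function(spec, spans = c(9, 9)) {
  stopifnot(inherits(spec, "temp_spectrum"))
  if (any(spans < 1) || any(spans %% 2 == 0)) {
    stop("`spans` must be odd positive integers")
  }
  kern <- 1
  for (s in spans) {
    kern <- stats::convolve(kern, rev(modified_daniell_weights(as.integer(s))),
                            type = "open")
  }
  p <- (length(kern) - 1L) / 2L
  x <- spec$density
  n <- length(x)
  if (p >= n) stop("`spans` too wide for a spectrum with ", n, " bins")
  if (p > 0L) {
    xp <- c(x[p:1], x, x[n:(n - p + 1L)])
    sm <- stats::filter(xp, kern, sides = 2)
    x <- as.numeric(sm[(p + 1L):(p + n)])
  }
  spec$density <- x
  spec$spans <- c(spec$spans, as.integer(spans))
  spec
}

#' Dominant spectral peaks, in period units
#'
#' Finds strict local maxima of the (smoothed) density whose topographic
#' prominence exceeds a threshold, and reports them as periods in hours,
#' sorted by density descending.
#'
#' @param spec A `temp_spectrum` (smooth it first for stable peaks).
#' @param min_prominence Minimum prominence, same units as the density
#'   (default 0: all strict local maxima).
#' @return A data frame `period_hours`, `frequency`, `density`,
#'   `prominence`, sorted by density descending; zero rows when the
#'   spectrum has no interior local maximum.
#' @export
find_peaks <- function(spec, min_prominence = 0) {
  stopifnot(inherits(spec, "temp_spectrum"))
  d <- spec$density
  n <- length(d)
  if (n < 3L) {
    return(data.frame(period_hours = numeric(0), frequency = numeric(0),
                      density = numeric(0), prominence = numeric(0)))
  }
  i <- 2:(n - 1)
  is_peak <- which(d[i] > d[i - 1] & d[i] > d[i + 1]) + 1L

  prom <- vapply(is_peak, function(p) {
    h <- d[p]
    saddles <- numeric(0)
    for (dir in c(-1L, 1L)) {
      j <- p
      lowest <- h
      repeat {
        j <- j + dir
        if (j < 1L || j > n) break
        if (d[j] > h) {
          saddles <- c(saddles, lowest)
          break
        }
        lowest <- min(lowest, d[j])
      }
    }
    if (length(saddles) == 0L) h - min(d) else h - max(saddles)
  }, numeric(1))

  keep <- prom >= min_prominence
  out <- data.frame(
    period_hours = spec$period_hours[is_peak][keep],
    frequency = spec$frequency[is_peak][keep],
    density = d[is_peak][keep],
    prominence = prom[keep]
  )
  out[order(-out$density), , drop = FALSE]
}
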