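#' Error-variance ratio for the Deming regression
#'
#' The errors-in-variables fit needs the ratio of the two series' error
#' variances. Following the coefficient-of-variation estimate
#' lambda = (CV_model * mean_model)^2 / (CV_obs * mean_obs)^2, which reduces
#' algebraically to the variance ratio sd(model)^2 / sd(obs)^2.
#'
#' @param ds A `paired_dataset`.
#' @return The scalar lambda (> 0).
#' @export
error_ratio_lambda <- function(ds) {
  if (nrow(ds) < 2L) stop("need at least 2 pairs")
  v_obs <- stats::var(ds$obs)
  if (v_obs == 0) stop("observed series is constant: lambda undefined")
  stats::var(ds$model) / v_obs
}

deming_slope <- function(sxx, syy, sxy, lambda) {
  (syy - lambda * sxx + sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
    (2 * sxy)
}

#' Deming (errors-in-variables) regression of model on observed temperature
#'
#' Fits `model = alpha * obs + beta` minimizing the generalized
#' perpendicular distance sum(model_i - yhat_i)^2 + lambda * (obs_i -
#' xhat_i)^2 under error-variance ratio `lambda`, via the closed-form slope
#' from the sample moments. With `lambda = 1` this is orthogonal (total
#' least squares) regression. The slope's significance against zero is
#' assessed with a jackknife standard error over pairs.
#'
#' @param ds A `paired_dataset`.
#' @param lambda Error-variance ratio; defaults to [error_ratio_lambda()].
#' @param jackknife Compute the jackknife SE and p-value? (Default `TRUE`;
#'   turn off for very large datasets where only the fit is needed.)
#' @return A `deming_fit` list: `alpha` (slope), `beta` (intercept, deg C),
#'   `lambda`, `n`, `se_alpha`, `p_value`.
#' @export
deming_fit <- function(ds, lambda = error_ratio_lambda(ds), jackknife = TRUE) {
  n <- nrow(ds)
  if (n < 3L) stop("need at least 3 pairs for a Deming fit")
  if (lambda <= 0) stop("`lambda` must be positive")
  x <- ds$obs
  y <- ds$model
  sxx <- stats::var(x)
  syy <- stats::var(y)
  sxy <- stats::cov(x, y)
  if (sxy == 0) stop("zero covariance between observed and model values: slope undefined")
  alpha <- deming_slope(sxx, syy, sxy, lambda)
  beta <- mean(y) - alpha * mean(x)

  se <- NA_real_
  p <- NA_real_
  if (jackknife) {
    # leave-one-out slopes via moment downdating (vectorized)
    Sx <- sum(x); Sy <- sum(y)
    Sxx <- sum(x^2); Syy <- sum(y^2); Sxy <- sum(x * y)
    n1 <- n - 1
    mx <- (Sx - x) / n1
    my <- (Sy - y) / n1
    cxx <- (Sxx - x^2) / n1 - mx^2
    cyy <- (Syy - y^2) / n1 - my^2
    cxy <- (Sxy - x * y) / n1 - mx * my
    ok <- cxy != 0
    a_i <- rep(NA_real_, n)
    a_i[ok] <- deming_slope(cxx[ok], cyy[ok], cxy[ok], lambda)
    a_bar <- mean(a_i, na.rm = TRUE)
    se <- sqrt((n - 1) / n * sum((a_i - a_bar)^2, na.rm = TRUE))
    p <- if (se > 0) 2 * stats::pt(abs(alpha) / se, df = n - 1, lower.tail = FALSE) else 0
  }

  structure(
    list(alpha = alpha, beta = beta, lambda = lambda, n = n,
         se_alpha = se, p_value = p),
    class = "deming_fit"
  )
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf(
    "<deming_fit> model = %.4f * obs + %.4f  (lambda = %.3f, n = %d, p = %.3g)\n",
    x$alpha, x$beta, x$lambda, x$n, x$p_value
  ))
  invisible(x)
}

#' Pairwise agreement statistics
#'
#' Computes the four standard pairwise skill metrics between model and
#' observed temperatures: Pearson correlation r, bias = mean(model - obs)
#' (positive = model warm), mean absolute error, and root mean squared
#' error. On every dataset `|bias| <= mae <= rmse`.
#'
#' @param ds A `paired_dataset`.
#' @param group_key Optional label carried into the result.
#' @return A `skill_report` list: `r`, `bias`, `mae`, `rmse` (deg C), `n`,
#'   `group_key`. `r` is `NA` when either series is constant.
#' @export
skill_summary <- function(ds, group_key = NA_character_) {
  n <- nrow(ds)
  if (n < 1L) stop("empty dataset")
  d <- ds$model - ds$obs
  r <- if (n >= 2L && stats::sd(ds$obs) > 0 && stats::sd(ds$model) > 0) {
    stats::cor(ds$obs, ds$model)
  } else {
    NA_real_
  }
  structure(
    list(r = r, bias = mean(d), mae = mean(abs(d)), rmse = sqrt(mean(d^2)),
         n = n, group_key = group_key),
    class = "skill_report"
  )
}

#' @export
print.skill_report <- function(x, ...) {
  cat(sprintf(
    "<skill_report>%s r = %.3f, bias = %.3f, MAE = %.3f, RMSE = %.3f degC (n = %d)\n",
    if (is.na(x$group_key)) "" else paste0(" [", x$group_key, "]"),
    x$r, x$bias, x$mae, x$rmse, x$n
  ))
  invisible(x)
}

#' Taylor-diagram statistics
#'
#' Correlation, the two standard deviations (sample, n-1 convention), their
#' ratio sd_model/sd_obs, and the centered RMS difference (computed after
#' removing each series' own mean, so additive offsets do not contribute).
#' The statistics satisfy the diagram's law-of-cosines identity
#' crmsd^2 = sd_model^2 + sd_obs^2 - 2 sd_model sd_obs r.
#'
#' @param ds A `paired_dataset`.
#' @return A `taylor_stat` list: `r`, `sd_obs`, `sd_model`, `sd_ratio`,
#'   `crmsd`, `crmsd_norm` (crmsd / sd_obs), `n`.
#' @export
taylor_stats <- function(ds) {
  n <- nrow(ds)
  if (n < 2L) stop("need at least 2 pairs")
  sd_o <- stats::sd(ds$obs)
  if (sd_o == 0) stop("observed series is constant: Taylor statistics undefined")
  sd_m <- stats::sd(ds$model)
  r <- if (sd_m > 0) stats::cor(ds$obs, ds$model) else NA_real_
  dd <- (ds$model - mean(ds$model)) - (ds$obs - mean(ds$obs))
  crmsd <- sqrt(sum(dd^2) / (n - 1))
  structure(
    list(r = r, sd_obs = sd_o, sd_model = sd_m, sd_ratio = sd_m / sd_o,
         crmsd = crmsd, crmsd_norm = crmsd / sd_o, n = n),
    class = "taylor_stat"
  )
}

#' @export
print.taylor_stat <- function(x, ...) {
  cat(sprintf(
    "<taylor_stat> r = %.3f, sd ratio = %.3f, centered RMSD = %.3f degC (n = %d)\n",
    x$r, x$sd_ratio, x$crmsd, x$n
  ))
  invisible(x)
}

skill_row <- function(ds, key) {
  s <- skill_summary(ds, group_key = key)
  t <- tryCatch(taylor_stats(ds), error = function(e) NULL)
  data.frame(
    group = key, n = s$n, r = s$r, bias = s$bias, mae = s$mae, rmse = s$rmse,
    sd_obs = if (is.null(t)) NA_real_ else t$sd_obs,
    sd_model = if (is.null(t)) NA_real_ else t$sd_model,
    sd_ratio = if (is.null(t)) NA_real_ else t$sd_ratio,
    crmsd = if (is.null(t)) NA_real_ else t$crmsd,
    crmsd_norm = if (is.null(t)) NA_real_ else t$crmsd_norm,
    stringsAsFactors = FALSE
  )
}

#' Skill and Taylor statistics by spatial or temporal grouping
#'
#' Splits the paired dataset by depth, distance-to-shore band, island,
#' season (calendar quarters JFM/AMJ/JAS/OND) or year, applying the
#' spin-up exclusion first, and computes [skill_summary()] and
#' [taylor_stats()] per group. Taylor normalization (`crmsd_norm`,
#' `sd_ratio`) divides by each group's own observed standard deviation.
#'
#' @param ds A `paired_dataset`.
#' @param grouping One of `"depth"`, `"distance_band"`, `"island"`,
#'   `"season"`, `"year"`.
#' @param min_n Groups with fewer matchups are flagged (`small = TRUE`),
#'   default 10.
#' @param distance_breaks Band edges in metres for
#'   `grouping = "distance_band"`; default: quartiles of the data.
#' @param spinup_cutoff Passed to [exclude_spinup()]; `NULL` disables the
#'   exclusion.
#' @return A data frame with one row per group: the group key, `n`, the four
#'   skill metrics, the Taylor statistics, and a `small` flag.
#' @export
grouped_skill <- function(ds,
                          grouping = c("depth", "distance_band", "island",
                                       "season", "year"),
                          min_n = 10, distance_breaks = NULL,
                          spinup_cutoff = "2011-01-01 00:00:00") {
  grouping <- match.arg(grouping)
  if (!is.null(spinup_cutoff)) ds <- exclude_spinup(ds, spinup_cutoff)
  if (nrow(ds) == 0L) stop("no matchups remain after the spin-up exclusion")

  key <- switch(grouping,
    depth = sprintf("%g m", ds$depth_m),
    distance_band = {
      if (all(is.na(ds$distance_to_shore_m))) {
        stop("distance_to_shore_m is missing from the dataset")
      }
      if (is.null(distance_breaks)) {
        distance_breaks <- unique(stats::quantile(ds$distance_to_shore_m,
                                                  c(0, .25, .5, .75, 1),
                                                  na.rm = TRUE))
      }
      as.character(cut(ds$distance_to_shore_m, distance_breaks,
                       include.lowest = TRUE, dig.lab = 6))
    },
    island = as.character(ds$island),
    season = ds$season,
    year = as.character(ds$year)
  )
  key[is.na(key)] <- "(missing)"
  groups <- split(seq_len(nrow(ds)), factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(names(groups), function(k) {
    skill_row(ds[groups[[k]], , drop = FALSE], k)
  }))
  out$small <- out$n < min_n
  rownames(out) <- NULL
  out
}
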