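#' Generalized additive model of model temperature bias
#'
#' Models per-matchup bias (model - observed, deg C) as an additive function
#' of depth (cubic regression spline), distance to shore (cubic regression
#' spline), day of year (cyclic cubic spline with the cycle closed between
#' day 1 and day 366), year (categorical, baseline 2011 when present) and a
#' latitude-longitude tensor-product surface, with a Gaussian family and
#' identity link. Smoothing parameters are selected by REML.
#'
#' Terms whose predictor has too few distinct values are dropped with a
#' warning (a spline needs at least 3 distinct values; the year factor needs
#' 2 levels). Basis dimensions shrink automatically when a predictor has
#' fewer unique values than the requested basis size.
#'
#' @param ds A `paired_dataset`; the spin-up exclusion is applied first.
#' @param k_univariate Basis dimension for the univariate smooths (default 10).
#' @param k_tensor Total basis dimension for the lat-lon tensor surface
#'   (default 25, i.e. 5 per margin).
#' @param spinup_cutoff Passed to [exclude_spinup()]; `NULL` disables it.
#' @return A `bias_model` list wrapping the fitted `mgcv::gam` object
#'   (`$fit`), the terms retained (`$terms_used`), per-predictor observed
#'   ranges (`$ranges`), the year baseline, and `$n`.
#' @export
fit_bias_gam <- function(ds, k_univariate = 10, k_tensor = 25,
                         spinup_cutoff = "2011-01-01 00:00:00") {
  if (!is.null(spinup_cutoff)) ds <- exclude_spinup(ds, spinup_cutoff)
  if (nrow(ds) < 50L) stop("too few matchups to fit the bias surface")

  d <- data.frame(
    bias = ds$model - ds$obs,
    depth_m = ds$depth_m,
    distance_to_shore_m = ds$distance_to_shore_m,
    doy = ds$doy,
    year = factor(ds$year),
    lat = ds$lat,
    lon = ds$lon
  )

  terms_used <- character(0)
  pieces <- character(0)
  add_smooth <- function(var, bs, k) {
    nu <- length(unique(d[[var]]))
    if (anyNA(d[[var]]) || nu < 3L) {
      warning("dropping smooth term for `", var, "` (", nu, " distinct value(s))")
      return(NULL)
    }
    k <- min(k, nu)
    sprintf("s(%s, bs = \"%s\", k = %d)", var, bs, k)
  }
  for (spec in list(c("depth_m", "cr"), c("distance_to_shore_m", "cr"))) {
    p <- add_smooth(spec[1], spec[2], k_univariate)
    if (!is.null(p)) {
      pieces <- c(pieces, p)
      terms_used <- c(terms_used, spec[1])
    }
  }
  p <- add_smooth("doy", "cc", k_univariate)
  if (!is.null(p)) {
    pieces <- c(pieces, p)
    terms_used <- c(terms_used, "doy")
  }
  baseline_year <- NULL
  if (nlevels(d$year) >= 2L) {
    if ("2011" %in% levels(d$year)) d$year <- stats::relevel(d$year, "2011")
    baseline_year <- levels(d$year)[1]
    pieces <- c(pieces, "year")
    terms_used <- c(terms_used, "year")
  } else {
    warning("single year of data: year term dropped")
  }
  n_loc <- nrow(unique(d[c("lat", "lon")]))
  if (!anyNA(d$lat) && !anyNA(d$lon) && n_loc >= 9L) {
    k_m <- max(3L, min(floor(sqrt(k_tensor)), floor(sqrt(n_loc))))
    pieces <- c(pieces, sprintf("te(lon, lat, k = c(%d, %d))", k_m, k_m))
    terms_used <- c(terms_used, "latlon")
  } else {
    warning("too few distinct locations (", n_loc, "): lat-lon surface dropped")
  }
  if (length(pieces) == 0L) stop("no usable predictors: bias surface is rank deficient")

  fml <- stats::as.formula(paste("bias ~", paste(pieces, collapse = " + ")))
  fit <- mgcv::gam(fml, data = d, family = stats::gaussian(),
                   method = "REML", knots = list(doy = c(1, 366)))

  ranges <- lapply(c("depth_m", "distance_to_shore_m", "doy", "lat", "lon"),
                   function(v) range(d[[v]]))
  names(ranges) <- c("depth_m", "distance_to_shore_m", "doy", "lat", "lon")

  structure(
    list(fit = fit, terms_used = terms_used, ranges = ranges,
         baseline_year = baseline_year, n = nrow(d)),
    class = "bias_model"
  )
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf(
    "<bias_model> n = %d, terms: %s\n  intercept = %.3f degC, deviance explained = %.1f%%\n",
    x$n, paste(x$terms_used, collapse = ", "),
    stats::coef(x$fit)[1], 100 * deviance_explained(x)
  ))
  invisible(x)
}

#' Fraction of deviance explained by the bias model
#'
#' `1 - residual deviance / null deviance`, in \[0, 1\].
#'
#' @param model A `bias_model`.
#' @return Scalar fraction.
#' @export
deviance_explained <- function(model) {
  stopifnot(inherits(model, "bias_model"))
  as.numeric(summary(model$fit)$dev.expl)
}

term_label <- function(model, predictor) {
  labs <- vapply(model$fit$smooth, function(s) s$label, character(1))
  want <- switch(predictor,
    depth_m = "s(depth_m)",
    distance_to_shore_m = "s(distance_to_shore_m)",
    doy = "s(doy)",
    latlon = "te(lon,lat)",
    stop("unknown predictor: ", predictor)
  )
  if (!want %in% labs) stop("predictor `", predictor, "` was not fitted in the model")
  want
}

#' Centered partial effect of one predictor on model bias
#'
#' Evaluates one fitted term over a grid with pointwise 95% confidence
#' bands. Smooth partial effects are centered to mean zero over the data
#' (the identifiability constraint absorbed by the intercept); the year
#' term returns discrete offsets relative to the baseline year.
#'
#' @param model A `bias_model`.
#' @param predictor One of `"depth_m"`, `"distance_to_shore_m"`, `"doy"`,
#'   `"year"`, `"latlon"`.
#' @param grid Predictor values to evaluate. Default: 200 points over the
#'   observed range (ignored for `"year"`). For `"latlon"` supply a data
#'   frame with `lon` and `lat` columns.
#' @param extrapolation_margin Allowed excursion beyond the observed range,
#'   as a fraction of the range (default 0.05); grids beyond it are refused.
#' @return A data frame: `predictor`, `grid` (or `year`/`lon`+`lat`),
#'   `effect`, `ci_low`, `ci_high` (deg C).
#' @export
partial_effect <- function(model, predictor, grid = NULL,
                           extrapolation_margin = 0.05) {
  stopifnot(inherits(model, "bias_model"))
  if (!predictor %in% model$terms_used) {
    stop("predictor `", predictor, "` was not fitted in the model")
  }
  fit <- model$fit
  mf <- fit$model

  if (predictor == "year") {
    cf <- stats::coef(fit)
    vc <- diag(fit$Vp)
    idx <- grep("^year", names(cf))
    yrs <- sub("^year", "", names(cf)[idx])
    out <- data.frame(
      predictor = "year",
      year = c(model$baseline_year, yrs),
      effect = c(0, unname(cf[idx])),
      se = c(0, sqrt(vc[idx])),
      stringsAsFactors = FALSE
    )
    out$ci_low <- out$effect - 1.96 * out$se
    out$ci_high <- out$effect + 1.96 * out$se
    return(out)
  }

  ref_row <- data.frame(
    depth_m = stats::median(mf$depth_m %||% 15),
    distance_to_shore_m = stats::median(mf$distance_to_shore_m %||% 500),
    doy = stats::median(mf$doy %||% 183),
    year = factor(model$baseline_year %||% "2011"),
    lat = stats::median(mf$lat %||% 21),
    lon = stats::median(mf$lon %||% -157)
  )

  if (predictor == "latlon") {
    if (is.null(grid)) {
      grid <- expand.grid(
        lon = seq(model$ranges$lon[1], model$ranges$lon[2], length.out = 20),
        lat = seq(model$ranges$lat[1], model$ranges$lat[2], length.out = 20)
      )
    }
    nd <- ref_row[rep(1, nrow(grid)), , drop = FALSE]
    nd$lon <- grid$lon
    nd$lat <- grid$lat
  } else {
    rng <- model$ranges[[predictor]]
    if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 200)
    margin <- extrapolation_margin * diff(rng)
    if (any(grid < rng[1] - margin | grid > rng[2] + margin)) {
      stop("grid extends beyond the observed range of `", predictor,
           "` (+/- the extrapolation margin)")
    }
    nd <- ref_row[rep(1, length(grid)), , drop = FALSE]
    nd[[predictor]] <- grid
  }
  rownames(nd) <- NULL

  lab <- term_label(model, predictor)
  pr <- mgcv::predict.gam(fit, newdata = nd, type = "terms",
                          terms = lab, se.fit = TRUE)
  eff <- as.numeric(pr$fit[, lab])
  se <- as.numeric(pr$se.fit[, lab])
  out <- if (predictor == "latlon") {
    data.frame(predictor = "latlon", lon = grid$lon, lat = grid$lat,
               effect = eff, stringsAsFactors = FALSE)
  } else {
    data.frame(predictor = predictor, grid = grid, effect = eff,
               stringsAsFactors = FALSE)
  }
  out$ci_low <- eff - 1.96 * se
  out$ci_high <- eff + 1.96 * se
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
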