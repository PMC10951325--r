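# naive two-pass loop implementation of the four pairwise metrics
naive_skill <- function(obs, model) {
  n <- length(obs)
  mo <- sum(obs) / n
  mm <- sum(model) / n
  num <- 0; do2 <- 0; dm2 <- 0; b <- 0; a <- 0; q <- 0
  for (i in seq_len(n)) {
    num <- num + (obs[i] - mo) * (model[i] - mm)
    do2 <- do2 + (obs[i] - mo)^2
    dm2 <- dm2 + (model[i] - mm)^2
    d <- model[i] - obs[i]
    b <- b + d; a <- a + abs(d); q <- q + d^2
  }
  list(r = num / sqrt(do2 * dm2), bias = b / n, mae = a / n, rmse = sqrt(q / n))
}

# generalized Deming distance: residual of the perpendicular projection
deming_objective <- function(alpha, beta, x, y, lambda) {
  sum(lambda * (y - alpha * x - beta)^2 / (lambda + alpha^2))
}

test_that("lambda is the model/observed variance ratio", {
  ds <- random_pairs(50, seed = 2)
  same <- paired_dataset(data.frame(site_id = "S", time = ds$time,
                                    obs = ds$obs, model = ds$obs))
  expect_equal(error_ratio_lambda(same), 1)

  dbl <- paired_dataset(data.frame(site_id = "S", time = ds$time,
                                   obs = ds$obs, model = 2 * ds$obs))
  expect_equal(error_ratio_lambda(dbl), 4)

  tri <- paired_dataset(data.frame(
    site_id = "S", time = ds$time[1:3],
    obs = c(25, 26, 27), model = c(25, 26, 30)
  ))
  # direct arithmetic: sample variances 1 and 7
  expect_equal(error_ratio_lambda(tri), 7 / 1)

  flat <- paired_dataset(data.frame(site_id = "S", time = ds$time[1:3],
                                    obs = rep(25, 3), model = c(25, 26, 30)))
  expect_error(error_ratio_lambda(flat), "constant")
})

test_that("Deming regression recovers exact lines for any lambda", {
  ds <- random_pairs(40, seed = 3)
  for (lam in c(0.3, 1, 4)) {
    ident <- paired_dataset(data.frame(site_id = "S", time = ds$time,
                                       obs = ds$obs, model = ds$obs))
    f <- deming_fit(ident, lambda = lam, jackknife = FALSE)
    expect_equal(f$alpha, 1, tolerance = 1e-10)
    expect_equal(f$beta, 0, tolerance = 1e-9)

    lin <- paired_dataset(data.frame(site_id = "S", time = ds$time,
                                     obs = ds$obs, model = 1.2 * ds$obs - 3))
    f2 <- deming_fit(lin, lambda = lam, jackknife = FALSE)
    expect_equal(f2$alpha, 1.2, tolerance = 1e-10)
    expect_equal(f2$beta, -3, tolerance = 1e-8)
  }
})

test_that("the closed-form Deming fit matches brute-force grid minimization on an 8-point fixture", {
  x <- c(24.1, 24.9, 25.3, 25.8, 26.2, 26.9, 27.4, 28.0)
  y <- c(24.6, 24.7, 25.9, 25.6, 26.8, 26.7, 27.9, 28.4)
  ds <- paired_dataset(data.frame(
    site_id = "S", time = as.POSIXct("2013-01-01", tz = "UTC") + 10800 * 1:8,
    obs = x, model = y
  ))
  f <- deming_fit(ds, lambda = 1)

  # coarse-to-fine grid search over (alpha, gamma) where beta is offset by
  # gamma from the mean-anchored line (decorrelates the two axes)
  best <- c(alpha = 1, gamma = 0)
  width <- c(2, 5)
  for (pass in 1:6) {
    alphas <- seq(best[1] - width[1], best[1] + width[1], length.out = 81)
    gammas <- seq(best[2] - width[2], best[2] + width[2], length.out = 81)
    obj <- outer(alphas, gammas, Vectorize(function(a, g) {
      deming_objective(a, mean(y) - a * mean(x) + g, x, y, 1)
    }))
    k <- arrayInd(which.min(obj), dim(obj))
    best <- c(alphas[k[1]], gammas[k[2]])
    width <- width / 10
  }
  expect_equal(f$alpha, best[1], tolerance = 5e-4)
  expect_equal(f$beta, mean(y) - best[1] * mean(x) + best[2], tolerance = 5e-3)
  expect_lt(f$p_value, 0.001)
})

test_that("lambda = 1 Deming equals orthogonal regression from the principal axis", {
  ds <- random_pairs(200, seed = 7, sd = 1, model_sd = 1)
  ds$model <- 0.8 * ds$obs + 5 + rnorm(200, 0, 0.3)
  f <- deming_fit(ds, lambda = 1, jackknife = FALSE)
  ev <- eigen(cov(cbind(ds$obs, ds$model)))$vectors[, 1]
  expect_equal(f$alpha, ev[2] / ev[1], tolerance = 1e-10)
})

test_that("Deming slope approaches the OLS and inverse-OLS limits as lambda -> 0 and Inf", {
  ds <- random_pairs(300, seed = 8)
  ds$model <- 0.9 * ds$obs + 2 + rnorm(300, 0, 0.4)
  ols_yx <- unname(coef(lm(ds$model ~ ds$obs))[2])
  ols_xy_inv <- 1 / unname(coef(lm(ds$obs ~ ds$model))[2])
  a_small <- deming_fit(ds, lambda = 1e-8, jackknife = FALSE)$alpha
  a_large <- deming_fit(ds, lambda = 1e8, jackknife = FALSE)$alpha
  # lambda weights the obs-direction error: one limit is OLS of model on obs,
  # the other the inverse fit; the Deming slope always lies between them
  lims <- sort(c(ols_yx, ols_xy_inv))
  expect_equal(min(abs(a_small - lims)), 0, tolerance = 1e-4)
  expect_equal(min(abs(a_large - lims)), 0, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(a_small, a_large, tolerance = 1e-4)))
  mid <- deming_fit(ds, lambda = 1, jackknife = FALSE)$alpha
  expect_gt(mid, lims[1]); expect_lt(mid, lims[2])
})

test_that("swapping the series and inverting lambda inverts the fitted line", {
  ds <- random_pairs(150, seed = 9)
  ds$model <- 1.1 * ds$obs - 2 + rnorm(150, 0, 0.3)
  lam <- 2.5
  f <- deming_fit(ds, lambda = lam, jackknife = FALSE)
  swapped <- paired_dataset(data.frame(site_id = "S", time = ds$time,
                                       obs = ds$model, model = ds$obs))
  g <- deming_fit(swapped, lambda = 1 / lam, jackknife = FALSE)
  expect_equal(g$alpha, 1 / f$alpha, tolerance = 1e-6)
  expect_equal(g$beta, -f$beta / f$alpha, tolerance = 1e-6)
})

test_that("skill_summary matches the naive loop and handles degenerate inputs", {
  ds <- random_pairs(250, seed = 11, bias = 0.17)
  s <- skill_summary(ds)
  o <- naive_skill(ds$obs, ds$model)
  expect_equal(s$r, o$r, tolerance = 1e-12)
  expect_equal(s$bias, o$bias, tolerance = 1e-12)
  expect_equal(s$mae, o$mae, tolerance = 1e-12)
  expect_equal(s$rmse, o$rmse, tolerance = 1e-12)

  ident <- paired_dataset(data.frame(site_id = "S", time = ds$time,
                                     obs = ds$obs, model = ds$obs))
  si <- skill_summary(ident)
  expect_equal(si$r, 1)
  expect_equal(c(si$bias, si$mae, si$rmse), c(0, 0, 0))

  shift <- paired_dataset(data.frame(site_id = "S", time = ds$time,
                                     obs = ds$obs, model = ds$obs + 0.5))
  ss <- skill_summary(shift)
  expect_equal(ss$r, 1)
  expect_equal(c(ss$bias, ss$mae, ss$rmse), c(0.5, 0.5, 0.5))

  const <- paired_dataset(data.frame(site_id = "S", time = ds$time,
                                     obs = rep(25, 250), model = ds$model))
  sc <- skill_summary(const)
  expect_true(is.na(sc$r))
  expect_false(is.na(sc$rmse))
})

test_that("|bias| <= mae <= rmse on arbitrary datasets", {
  for (seed in 1:20) {
    ds <- random_pairs(60, seed = seed, bias = runif(1, -1, 1),
                       model_sd = runif(1, 0.1, 2))
    s <- skill_summary(ds)
    expect_lte(abs(s$bias), s$mae)
    expect_lte(s$mae, s$rmse)
  }
})

test_that("Taylor statistics satisfy the law-of-cosines identity and known transforms", {
  ds <- random_pairs(300, seed = 13, bias = 0.2, model_sd = 1.4)
  t1 <- taylor_stats(ds)
  expect_equal(t1$crmsd^2,
               t1$sd_model^2 + t1$sd_obs^2 - 2 * t1$sd_model * t1$sd_obs * t1$r,
               tolerance = 1e-9)

  ident <- paired_dataset(data.frame(site_id = "S", time = ds$time,
                                     obs = ds$obs, model = ds$obs))
  ti <- taylor_stats(ident)
  expect_equal(c(ti$sd_ratio, ti$r, ti$crmsd), c(1, 1, 0))

  shifted <- paired_dataset(data.frame(site_id = "S", time = ds$time,
                                       obs = ds$obs, model = ds$obs + 3))
  ts <- taylor_stats(shifted)
  expect_equal(c(ts$sd_ratio, ts$r, ts$crmsd), c(ti$sd_ratio, ti$r, ti$crmsd))

  doubled <- paired_dataset(data.frame(
    site_id = "S", time = ds$time,
    obs = ds$obs, model = mean(ds$obs) + 2 * (ds$obs - mean(ds$obs))
  ))
  td <- taylor_stats(doubled)
  expect_equal(td$sd_ratio, 2, tolerance = 1e-12)
  expect_equal(td$r, 1, tolerance = 1e-12)
  expect_equal(td$crmsd, td$sd_obs, tolerance = 1e-12)

  flat <- paired_dataset(data.frame(site_id = "S", time = ds$time,
                                    obs = rep(25, 300), model = ds$model))
  expect_error(taylor_stats(flat), "constant")
})

test_that("grouped skill recovers island-specific injected biases and groups correctly", {
  mk <- function(island, bias, seed, lat) {
    cfgs <- lapply(1:3, function(i) synthetic_site_config(
      site_id = paste0(island, i), island = island, lat = lat,
      end = "2013-03-01 00:00:00", sample_interval_min = 30
    ))
    arc <- make_paired_dataset(cfgs, model_error_config(constant_bias = bias),
                               seed = seed)
    pair_archive(arc$obs, arc$model)
  }
  ds <- paired_dataset(rbind(as.data.frame(mk("IslA", 0.1, 1, 20.7)),
                             as.data.frame(mk("IslB", 0.3, 2, 21.4))))
  tab <- grouped_skill(ds, "island", spinup_cutoff = NULL)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$bias[tab$group == "IslA"], 0.1, tolerance = 0.02)
  expect_equal(tab$bias[tab$group == "IslB"], 0.3, tolerance = 0.02)
  expect_false(any(tab$small))

  # a dataset spanning one July groups into the single season JAS
  july <- paired_dataset(data.frame(
    site_id = "S",
    time = as.POSIXct("2013-07-02", tz = "UTC") + 10800 * 0:99,
    obs = 25 + rnorm(100, 0, 0.2), model = 25 + rnorm(100, 0, 0.2)
  ))
  tab2 <- grouped_skill(july, "season", spinup_cutoff = NULL)
  expect_equal(tab2$group, "JAS")

  # single-site dataset grouped by island -> one row
  tab3 <- grouped_skill(july, "island", spinup_cutoff = NULL)
  expect_equal(nrow(tab3), 1)

  expect_error(grouped_skill(july, "watershed"), "arg")
})
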