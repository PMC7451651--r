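test_that("normality screening is calibrated on known distributions", {
  expect_error(normality_test(c(1, 2)), "at least 3")
  expect_error(normality_test(rep(5, 10)), "constant")

  pass_rate <- mean(withr::with_seed(11, {
    vapply(1:100, function(i)
      normality_test(stats::rnorm(500, 100, 10))$pass, logical(1))
  }))
  expect_gte(pass_rate, 0.9)

  fail_rate <- mean(withr::with_seed(12, {
    vapply(1:100, function(i) {
      r <- normality_test(stats::rlnorm(200, 0, 1.5))
      !r$pass && identical(r$recommendation, "log-transform")
    }, logical(1))
  }))
  expect_gte(fail_rate, 0.9)
})

test_that("Moran's I matches the brute-force double sum", {
  p <- price_points(c(0, 100, 100, 0), c(0, 0, 100, 100), c(10, 20, 30, 25))
  res <- morans_i(p, n_perm = 99, seed = 1)
  expect_equal(res$I, brute_force_moran(p$x, p$y, p$price), tolerance = 1e-12)
  expect_equal(res$expected_I, -1 / 3)
})

test_that("Moran screening detects structure and respects the null", {
  # smooth ramp: strong positive autocorrelation
  p <- withr::with_seed(21, {
    x <- stats::runif(60, 0, 1000); y <- stats::runif(60, 0, 1000)
    price_points(x, y, 100 + 0.2 * x + 0.1 * y + stats::rnorm(60, 0, 5))
  })
  res <- morans_i(p, seed = 2)
  expect_gt(res$I, 0)
  expect_lte(res$p_value, 0.05)

  # i.i.d. prices: I near its null expectation, mostly insignificant
  null_runs <- withr::with_seed(22, {
    lapply(1:40, function(i) {
      q <- price_points(stats::runif(100, 0, 1000), stats::runif(100, 0, 1000),
                        100 + stats::rnorm(100, 0, 10))
      morans_i(q, n_perm = 199, seed = i)
    })
  })
  Is <- vapply(null_runs, `[[`, numeric(1), "I")
  expect_lt(abs(mean(Is) - (-1 / 99)), 0.02)
  expect_gte(mean(vapply(null_runs, `[[`, numeric(1), "p_value") > 0.05), 0.9)

  expect_error(morans_i(price_points(1:5, 1:5, rep(2, 5))), "zero-variance")
})

test_that("empirical semivariogram reproduces hand-computable cases", {
  # two points, values 0 and 2 -> gamma = (1/2)(2)^2 / 1 = 2 in its bin
  p <- suppressWarnings(price_points(c(0, 100, 200), c(0, 0, 0), c(1, 3, 1)))
  emp <- empirical_semivariogram(p, n_bins = 1, max_lag = 150)
  expect_equal(emp$gamma, 2.0)  # pairs (1,2) and (2,3), both (z diff)^2 = 4
  expect_equal(emp$npairs, 2L)

  const <- price_points(stats::runif(10, 0, 100), stats::runif(10, 0, 100),
                        rep(7, 10) + 1e-12 * (1:10))
  expect_true(all(empirical_semivariogram(const)$gamma < 1e-20))

  coincident <- data.frame(x = rep(1, 4), y = rep(2, 4), price = 1:4)
  expect_error(empirical_semivariogram(coincident), "coincident")
})

test_that("variogram fitting inverts a noiseless model within 1%", {
  truth <- vgm_model("spherical", nugget = 10, psill = 100, range = 600)
  h <- seq(50, 950, length.out = 10)
  emp <- structure(
    data.frame(lag = h, gamma = vgm_gamma(truth, h), npairs = rep(100L, 10)),
    max_lag = 1000, n_bins = 10, n_points = NA,
    class = c("empirical_variogram", "data.frame"))
  fit <- fit_variogram(emp, "spherical")[[1]]
  expect_equal(fit$nugget, truth$nugget, tolerance = 0.01)
  expect_equal(fit$psill, truth$psill, tolerance = 0.01)
  expect_equal(fit$range, truth$range, tolerance = 0.01)

  # flat structure: the pure-nugget model wins with ~zero partial sill
  flat <- structure(
    data.frame(lag = h, gamma = rep(50, 10), npairs = rep(100L, 10)),
    max_lag = 1000, n_bins = 10, n_points = NA,
    class = c("empirical_variogram", "data.frame"))
  fits <- fit_variogram(flat, c("spherical", "pure_nugget"))
  expect_equal(fits$pure_nugget$wsse, 0, tolerance = 1e-9)
  expect_lte(fits$pure_nugget$wsse, fits$spherical$wsse + 1e-9)

  expect_error(fit_variogram(emp[1:2, ]), "3")
})

test_that("empirical variogram of a simulated field tracks the truth", {
  truth <- vgm_model("spherical", nugget = 0, psill = 1, range = 500)
  g <- grid_spec(200, 200, 15, origin = c(0, 3000))
  f <- simulate_grf(g, truth, seed = 31)
  xy <- cell_centers(g)
  idx <- withr::with_seed(32, sample(nrow(xy), 400))
  pts <- price_points(xy[idx, 1], xy[idx, 2], f[idx] + 10)
  emp <- empirical_semivariogram(pts)
  below <- emp$lag < truth$range & emp$lag > 100
  rel <- abs(emp$gamma[below] - vgm_gamma(truth, emp$lag[below])) /
    vgm_gamma(truth, emp$lag[below])
  expect_lt(stats::median(rel), 0.2)
})

test_that("kriging matches the brute-force full-system oracle", {
  model <- vgm_model("exponential", nugget = 3, psill = 80, range = 250)
  p <- toy_points(8, seed = 41)
  targets <- withr::with_seed(42,
    cbind(stats::runif(12, 0, 1000), stats::runif(12, 0, 1000)))
  got <- krige_at(p, model, targets)
  for (i in seq_len(nrow(targets))) {
    want <- brute_force_ok(p$x, p$y, p$price, model,
                           targets[i, 1], targets[i, 2])
    expect_equal(got$pred[i], want$pred, tolerance = 1e-6)
    expect_equal(got$variance[i], want$variance, tolerance = 1e-6)
  }
})

test_that("ordinary kriging is exact, unbiased and symmetric", {
  model <- vgm_model("spherical", nugget = 0, psill = 200, range = 400)
  # midpoint of two samples under any symmetric model is their mean
  p2 <- price_points(c(0, 100), c(0, 0), c(10, 20))
  expect_equal(krige_at(p2, model, cbind(50, 0))$pred, 15)

  p <- toy_points(25, seed = 43)
  at_data <- krige_at(p, model, cbind(p$x, p$y))
  expect_equal(at_data$pred, p$price, tolerance = 1e-6)
  # monotone information: variance at a sample site <= far-field variance
  far <- krige_at(p, model, cbind(1e5, 1e5))
  expect_true(all(at_data$variance <= far$variance + 1e-9))

  g <- grid_spec(12, 12, 90, origin = c(0, 1080))
  surf <- ordinary_kriging(p, model, g)
  expect_lt(attr(surf, "max_weight_sum_err"), 1e-8)
  expect_true(all(is.finite(surf$values)))
  expect_true(all(surf$variance >= 0))

  # finite neighborhood agrees with global when it includes all points
  surf_nb <- ordinary_kriging(p, model, g, max_neighbors = 25)
  expect_equal(surf_nb$values, surf$values, tolerance = 1e-9)
  # a restricted neighborhood still predicts sensibly
  surf_k <- ordinary_kriging(p, model, g, max_neighbors = 8)
  expect_lt(attr(surf_k, "max_weight_sum_err"), 1e-8)
  expect_lt(max(abs(surf_k$values - surf$values)), 3 * sqrt(200))
})

test_that("kriging beats inverse-distance weighting on a simulated field", {
  truth <- vgm_model("spherical", nugget = 0, psill = 900, range = 900)
  g <- grid_spec(100, 100, 15, origin = c(0, 1500))
  f <- simulate_grf(g, truth, seed = 51)
  xy <- cell_centers(g)
  idx <- withr::with_seed(52, sample(nrow(xy), 400))
  pts <- price_points(xy[idx, 1], xy[idx, 2], f[idx] + 200)
  hold <- withr::with_seed(53, sample(setdiff(seq_len(nrow(xy)), idx), 500))
  kr <- krige_at(pts, truth, xy[hold, , drop = FALSE])
  rmse_k <- sqrt(mean((kr$pred - (f[hold] + 200))^2))
  rmse_i <- sqrt(mean((idw_at(pts$x, pts$y, pts$price,
                              xy[hold, , drop = FALSE]) - (f[hold] + 200))^2))
  expect_lt(rmse_k, sqrt(900))
  expect_lt(rmse_k, rmse_i)
})

test_that("cross-validation ranks candidates and honors tie-breaks", {
  p <- toy_points(30, seed = 61)
  m1 <- vgm_model("spherical", nugget = 5, psill = 100, range = 300)

  single <- loo_cross_validate(p, list(m1))
  expect_length(single, 1)
  expect_true(is.finite(single[[1]]$loo_rmse))

  # candidates with identical semivariograms tie; ties break by fewer
  # parameters (pure nugget) then family order (spherical < exponential)
  flat_sph <- vgm_model("spherical", 25, 0, 300)
  flat_exp <- vgm_model("exponential", 25, 0, 300)
  flat_pn <- vgm_model("pure_nugget", 25, 0)
  ranked <- loo_cross_validate(p, list(flat_exp, flat_sph, flat_pn))
  expect_equal(ranked[[1]]$loo_rmse, ranked[[3]]$loo_rmse, tolerance = 1e-12)
  expect_equal(vapply(ranked, `[[`, character(1), "family"),
               c("pure_nugget", "spherical", "exponential"))
  expect_error(loo_cross_validate(toy_points(5), list(m1)), "10")

  # the LOO shortcut equals an explicit leave-one-out refit
  direct <- vapply(seq_len(nrow(p)), function(i)
    krige_at(p[-i, ], m1, cbind(p$x[i], p$y[i]))$pred, numeric(1))
  shortcut <- loo_cross_validate(p, list(m1))[[1]]$loo_rmse
  expect_equal(shortcut, sqrt(mean((p$price - direct)^2)), tolerance = 1e-8)
})
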