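## small aligned coarse grids for GWR tests
gwr_world <- function(n = 12, cell = 1000, f = function(x, y, e) 2 + 0.01 * e) {
  elev <- river_grid(matrix(runif(n * n, 0, 800), n, n), cell)
  xy <- grid_xy(elev)
  resp <- river_grid(matrix(f(xy[, 1], xy[, 2], as.vector(elev$values)),
                            n, n), cell)
  list(elev = elev, resp = resp)
}

test_that("gwr recovers an exact linear field and the OLS limit", {
  set.seed(1)
  w <- gwr_world()
  fit <- gwr_fit(w$resp, w$elev, bandwidth = 2000)
  expect_equal(fit$coef$slope, rep(0.01, nrow(fit$coef)), tolerance = 1e-9)
  expect_equal(fit$coef$intercept, rep(2, nrow(fit$coef)), tolerance = 1e-9)
  ## bandwidth -> infinity reproduces global OLS coefficients
  set.seed(2)
  noisy <- w$resp
  noisy$values <- noisy$values + rnorm(length(noisy$values), sd = 0.5)
  fit2 <- gwr_fit(noisy, w$elev, bandwidth = 1e9)
  ols <- stats::coef(stats::lm(as.vector(noisy$values) ~
                                 as.vector(w$elev$values)))
  expect_equal(fit2$coef$intercept, rep(unname(ols[1]), nrow(fit2$coef)),
               tolerance = 1e-6)
  expect_equal(fit2$coef$slope, rep(unname(ols[2]), nrow(fit2$coef)),
               tolerance = 1e-6)
  ## constant elevation in the window falls back to the local mean, flagged
  flat_e <- river_grid(matrix(100, 8, 8), 1000)
  r <- river_grid(matrix(rnorm(64), 8, 8), 1000)
  fit3 <- gwr_fit(r, flat_e, bandwidth = 3000)
  expect_true(all(fit3$coef$flagged))
  expect_true(all(fit3$coef$slope == 0))
})

test_that("gwr resolves a two-regime slope field at small bandwidth", {
  set.seed(3)
  n <- 16; cell <- 1000
  elev <- river_grid(matrix(runif(n * n, 0, 800), n, n), cell)
  xy <- grid_xy(elev)
  b <- ifelse(xy[, 1] < n / 2 * cell, 0.02, -0.01)
  resp <- river_grid(matrix(1 + b * as.vector(elev$values), n, n), cell)
  fit <- gwr_fit(resp, elev, bandwidth = 1500)
  left <- fit$coef$x < (n / 2 - 3) * cell
  right <- fit$coef$x > (n / 2 + 3) * cell
  expect_lt(abs(mean(fit$coef$slope[left]) - 0.02), 0.002)
  expect_lt(abs(mean(fit$coef$slope[right]) + 0.01), 0.002)
})

test_that("bandwidth selection: exact linear field ties to the smallest,
           varying field picks an interior bandwidth", {
  set.seed(4)
  w <- gwr_world()
  ## exact global linear field: all candidates give zero CV error -> ties
  ## break to the smallest candidate
  expect_equal(select_bandwidth(w$resp, w$elev, c(2000, 4000, 8000)), 2000)
  expect_equal(select_bandwidth(w$resp, w$elev, 3000), 3000)
  expect_error(select_bandwidth(w$resp, w$elev, numeric(0)), "candidate")
  ## spatially varying slope: selected bandwidth below the domain size
  n <- 16; cell <- 1000
  elev <- river_grid(matrix(runif(n * n, 0, 800), n, n), cell)
  xy <- grid_xy(elev)
  b <- 0.01 + 0.02 * sin(2 * pi * xy[, 1] / (n * cell))
  resp <- river_grid(matrix(b * as.vector(elev$values), n, n), cell)
  sel <- select_bandwidth(resp, elev, c(1000, 2000, 4000, 1e7))
  expect_lt(sel, n * cell)
})

test_that("variogram fitting: degenerate, white-noise and known-model
           recovery", {
  const <- data.frame(x = runif(20), y = runif(20), value = 5)
  vg0 <- fit_variogram(const)
  expect_equal(vg0$nugget + vg0$psill, 0)
  ## white noise: flat variogram at the variance
  set.seed(5)
  wn <- data.frame(x = runif(300, 0, 100), y = runif(300, 0, 100),
                   value = rnorm(300, sd = 2))
  vg1 <- fit_variogram(wn)
  expect_equal(vg1$nugget + vg1$psill, 4,
               tolerance = 0.2 * 4)   # sill ~ variance within 20 %
  ## draws from a known spherical model (sill 1, range 30): range within 30%
  set.seed(6)
  npt <- 200
  xy <- cbind(runif(npt, 0, 100), runif(npt, 0, 100))
  d <- as.matrix(stats::dist(xy))
  h <- pmin(d / 30, 1)
  C <- 1 - (1.5 * h - 0.5 * h^3)      # spherical covariance, sill 1
  L <- chol(C + diag(1e-8, npt))
  val <- drop(t(L) %*% rnorm(npt))
  vg2 <- fit_variogram(data.frame(x = xy[, 1], y = xy[, 2], value = val))
  expect_equal(vg2$range, 30, tolerance = 0.3 * 30)
  expect_error(fit_variogram(const[1:5, ]), "10 samples")
})

test_that("ordinary kriging is exact at samples, unbiased, and matches the
           hand-solved system", {
  set.seed(7)
  samp <- data.frame(x = runif(25, 0, 50), y = runif(25, 0, 50),
                     value = rnorm(25))
  vg <- structure(list(family = "exponential", nugget = 0.1, psill = 1,
                       range = 20), class = "variogram_model")
  ## exactness at sample points
  pred <- krige_surface(samp, vg, samp[, c("x", "y")])
  expect_equal(pred, samp$value, tolerance = 1e-8)
  ## constant samples -> constant surface
  sc <- transform(samp, value = 3.3)
  target <- river_grid(matrix(0, 10, 10), 5)
  expect_equal(krige_surface(sc, vg, target)$values,
               matrix(3.3, 10, 10), tolerance = 1e-8)
  ## three-point toy against the hand-built kriging system (linear-like
  ## exponential variogram), including the weight constraint
  s3 <- data.frame(x = c(0, 10, 20), y = c(0, 0, 0), value = c(1, 3, 2))
  g <- function(h) ifelse(h == 0, 0, 0.5 * (1 - exp(-3 * h / 40)))
  vg3 <- structure(list(family = "exponential", nugget = 0, psill = 0.5,
                        range = 40), class = "variogram_model")
  hand <- oracle_krige_point(s3$x, s3$y, s3$value, g, 7, 0)
  expect_equal(sum(hand$weights), 1, tolerance = 1e-10)
  got <- krige_surface(s3, vg3, cbind(7, 0))
  expect_equal(got, hand$pred, tolerance = 1e-9)
  ## duplicate coordinates are averaged with a warning
  dup <- rbind(samp, samp[1, ])
  expect_warning(krige_surface(dup, vg, cbind(25, 25)), "duplicate")
})

test_that("station correction matches stations exactly and shifts a uniform
           bias", {
  set.seed(8)
  g <- river_grid(matrix(rnorm(400), 20, 20), 100)
  cells <- sample.int(400, 12)
  xy <- grid_xy(g, cells)
  ## uniform +1 bias at all stations
  st <- data.frame(x = xy[, 1], y = xy[, 2], value = g$values[cells] + 1)
  out <- station_correction(g, st)
  expect_equal(out$values[cells], st$value, tolerance = 1e-6)
  expect_equal(mean(out$values - g$values), 1, tolerance = 0.25)
  ## zero residuals: identity
  st0 <- data.frame(x = xy[, 1], y = xy[, 2], value = g$values[cells])
  expect_equal(station_correction(g, st0)$values, g$values,
               tolerance = 1e-9)
  ## stations outside the grid are dropped with a warning
  stx <- rbind(st, data.frame(x = -500, y = -500, value = 0))
  expect_warning(station_correction(g, stx), "outside")
})

test_that("downscale_predict combines surfaces and floors precipitation", {
  dem <- river_grid(matrix(runif(64, 0, 100), 8, 8), 50)
  a <- river_grid(matrix(1, 8, 8), 50)
  b <- river_grid(matrix(-0.5, 8, 8), 50)
  out <- downscale_predict(a, b, dem)
  expect_equal(out$values, 1 - 0.5 * dem$values)
  expect_true(all(downscale_predict(a, b, dem, floor_zero = TRUE)$values
                  >= 0))
  ## zero slope surfaces: prediction is the intercept everywhere
  z <- river_grid(matrix(0, 8, 8), 50)
  expect_equal(downscale_predict(a, z, dem)$values, matrix(1, 8, 8))
  bad <- river_grid(matrix(0, 9, 9), 50)
  expect_error(downscale_predict(a, b, bad), "aligned")
})

test_that("end-to-end downscaling recovers a lapse-rate climate", {
  cfg <- tiny_world(seed = 11)
  dem <- make_dem(cfg)
  clim <- make_monthly_climate(dem, cfg)
  st <- clim$stations[clim$stations$variable == "tmin" &
                        clim$stations$month == 1, c("x", "y", "value")]
  out <- downscale_surface(climate_layer(clim$coarse, "tmin", 1),
                           clim$dem_coarse, dem, stations = st)
  ## truth without noise: January sea-level tmin minus lapse x elevation
  truth <- (14 + cfg$seasonal_temp_amplitude) - 5 -
    cfg$lapse_rate * dem$values / 1000
  rmse <- sqrt(mean((out$values - truth)^2))
  expect_lt(rmse, cfg$temp_noise_sd)
  fitl <- stats::lm(as.vector(out$values) ~ as.vector(dem$values))
  expect_equal(unname(stats::coef(fitl)[2]) * 1000, -cfg$lapse_rate,
               tolerance = 0.05 * cfg$lapse_rate)
})
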