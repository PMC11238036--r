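toy_data <- function(n = 200, seed = 31) {
  set.seed(seed)
  bg <- data.frame(a = runif(n), b = rnorm(n))
  pres <- bg[sample(n, 40, prob = exp(-((bg$a - 0.7) / 0.2)^2)), ]
  list(bg = bg, pres = pres)
}

test_that("build_features expands the requested classes", {
  d <- toy_data()
  expect_length(build_features(d$bg, "l")$defs, 2)       # one per predictor
  expect_length(build_features(d$bg["a"], "linear")$defs, 1)
  ## 2 predictors, linear + quadratic + product: 2 + 2 + 1 = 5
  expect_length(build_features(d$bg, c("linear", "quadratic",
                                       "product"))$defs, 5)
  ## constant predictor dropped with a warning
  d2 <- cbind(d$bg, cst = 1)
  expect_warning(fs <- build_features(d2, "l"), "cst")
  expect_length(fs$defs, 2)
  ## all features in [0, 1] on background
  fs3 <- build_features(d$bg, "lqpht")
  F3 <- feature_matrix(fs3, d$bg)
  expect_true(all(F3 >= 0 & F3 <= 1))
})

test_that("hinge features are the documented piecewise ramps", {
  bg <- data.frame(x = seq(0, 10, length.out = 101))
  fs <- build_features(bg, "hinge", knots_per_hinge = 5)
  knots <- stats::quantile(bg$x, seq(0, 1, length.out = 7)[2:6],
                           names = FALSE)
  Fm <- feature_matrix(fs, bg)
  fwd_names <- grep("h\\(x>", colnames(Fm))
  for (j in seq_along(fwd_names)) {
    k <- knots[j]
    manual <- pmax(0, (bg$x - k) / (10 - k))
    ## min-max rescaling on background is a no-op for a ramp hitting [0,1]
    expect_equal(unname(Fm[, fwd_names[j]]), manual, tolerance = 1e-12)
  }
  rev_names <- grep("h\\(x<", colnames(Fm))
  expect_length(rev_names, 5)
  manual_rev <- pmax(0, (knots[2] - bg$x) / (knots[2] - 0))
  expect_equal(unname(Fm[, rev_names[2]]), manual_rev, tolerance = 1e-12)
})

test_that("all-constant predictors give the uniform model", {
  bg <- data.frame(x = rep(2, 50))
  pres <- bg[1:10, , drop = FALSE]
  expect_warning(fs <- build_features(bg, "lq"), "dropped")
  m <- fit_maxent(pres, bg, fs)
  expect_length(m$lambda, 0)
  expect_equal(predict(m, bg, "raw"), rep(1 / 50, 50))
})

test_that("beta = 0 satisfies the moment-matching KKT condition", {
  ## single binary feature: the fitted expectation over the Gibbs
  ## distribution equals the empirical presence mean
  bg <- data.frame(x = rep(c(0, 1), each = 50))
  pres <- data.frame(x = rep(c(0, 1), c(10, 40)))
  fs <- build_features(bg, "l")
  m <- fit_maxent(pres, bg, fs, beta = 0, tol = 1e-12)
  r <- predict(m, bg, "raw")
  expect_equal(sum(r * feature_matrix(fs, bg)[, 1]), 0.8,
               tolerance = 1e-6)
  ## and on a richer toy with two features
  d <- toy_data()
  fs2 <- build_features(d$bg, "l")
  m2 <- fit_maxent(d$pres, d$bg, fs2, beta = 0, tol = 1e-12)
  r2 <- predict(m2, d$bg, "raw")
  Fb <- feature_matrix(fs2, d$bg)
  Fp <- feature_matrix(fs2, d$pres)
  expect_equal(drop(crossprod(Fb, r2)), colMeans(Fp), tolerance = 1e-6)
})

test_that("fitted weights match the generic convex-optimizer oracle", {
  ## 10-background-point toy, 2 features, beta = 1
  set.seed(32)
  bg <- data.frame(a = seq(0, 1, length.out = 10),
                   b = c(0.2, 0.9, 0.1, 0.5, 0.8, 0.3, 0.6, 0.2, 0.9, 0.4))
  pres <- bg[c(7, 8, 9, 10, 9), ]
  fs <- build_features(bg, "l")
  m <- fit_maxent(pres, bg, fs, beta = 1, tol = 1e-12)
  lam_oracle <- oracle_maxent_lambda(feature_matrix(fs, pres),
                                     feature_matrix(fs, bg), m$beta_j)
  expect_equal(unname(m$lambda), lam_oracle, tolerance = 1e-4)
  ## larger toy with quadratic features
  d <- toy_data(n = 60)
  fs2 <- build_features(d$bg, "lq")
  m2 <- fit_maxent(d$pres, d$bg, fs2, beta = 1, tol = 1e-12)
  lam2 <- oracle_maxent_lambda(feature_matrix(fs2, d$pres),
                               feature_matrix(fs2, d$bg), m2$beta_j)
  expect_equal(unname(m2$lambda), lam2, tolerance = 1e-4)
})

test_that("raw predictions normalize over the background", {
  d <- toy_data()
  for (cl in list("l", "lq", "lqh")) {
    m <- fit_maxent(d$pres, d$bg, build_features(d$bg, cl))
    expect_equal(sum(predict(m, d$bg, "raw")), 1, tolerance = 1e-9)
  }
})

test_that("output transforms follow the stated formulas and preserve
           order", {
  d <- toy_data()
  m <- fit_maxent(d$pres, d$bg, build_features(d$bg, "lq"))
  r <- predict(m, d$bg, "raw")
  ## entropy recomputed by enumeration
  H <- -sum(r * log(r))
  expect_equal(m$H, H, tolerance = 1e-10)
  expect_equal(predict(m, d$bg, "cloglog"), 1 - exp(-r * exp(H)),
               tolerance = 1e-12)
  expect_equal(predict(m, d$bg, "logistic"),
               r * exp(H) / (1 + r * exp(H)), tolerance = 1e-12)
  ## monotone map: ordering preserved
  expect_identical(order(predict(m, d$bg, "cloglog")), order(r))
  ## uniform model raw = 1/N exactly
  mu <- suppressWarnings(fit_maxent(d$pres[, 1, drop = FALSE] * 0 + 1,
                                    d$bg[, 1, drop = FALSE] * 0 + 1,
                                    beta = 1))
  expect_equal(predict(mu, d$bg[, 1, drop = FALSE]* 0 + 1, "raw"),
               rep(1 / nrow(d$bg), nrow(d$bg)))
})

test_that("maxent_aicc follows the stated arithmetic", {
  ## k = 3, lnL = -100, n = 20 -> AICc = 206 + 24/16 = 207.5
  expect_equal(2 * 3 - 2 * (-100) + 2 * 3 * 4 / (20 - 3 - 1), 207.5)
  d <- toy_data()
  m <- fit_maxent(d$pres, d$bg, build_features(d$bg, "lq"))
  ic <- maxent_aicc(m, d$pres, d$bg)
  ## lnL equals the brute-force sum of log raw over presences
  lnl <- sum(log(predict(m, d$pres, "raw")))
  expect_equal(ic$loglik, lnl, tolerance = 1e-9)
  k <- sum(m$lambda != 0)
  expect_identical(ic$k, k)
  expect_equal(ic$aicc, 2 * k - 2 * lnl + 2 * k * (k + 1) /
                 (nrow(d$pres) - k - 1))
  ## n <= k + 1 flags the candidate invalid
  ic2 <- maxent_aicc(m, d$pres[seq_len(k), ], d$bg)
  expect_false(ic2$valid)
  expect_true(is.na(ic2$aicc))
})

test_that("solver objective decreases monotonically and the regularization
           path is sane", {
  d <- toy_data()
  fs <- build_features(d$bg, "lqh")
  m <- fit_maxent(d$pres, d$bg, fs, beta = 1)
  expect_true(all(diff(m$objective_trace) <= 1e-9))
  ## increasing beta never increases the active-feature count (checked on
  ## a well-separated grid of multipliers)
  ks <- vapply(c(0.5, 2, 8, 32, 128), function(b)
    sum(fit_maxent(d$pres, d$bg, build_features(d$bg, "lq"),
                   beta = b)$lambda != 0), numeric(1))
  expect_true(all(diff(ks) <= 0))
  expect_error(fit_maxent(d$pres, d$bg, fs, beta = -1), "beta")
})

test_that("model serialization writes the lambdas file and header", {
  d <- toy_data()
  m <- fit_maxent(d$pres, d$bg, build_features(d$bg, "l"))
  base <- tempfile()
  write_maxent_model(m, base)
  lam <- utils::read.csv(paste0(base, ".lambdas.csv"))
  expect_equal(lam$lambda, unname(m$lambda))
  hdr <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(hdr$Z, m$Z)
  expect_equal(hdr$transform, "cloglog")
})
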