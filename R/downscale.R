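## Statistical downscaling of coarse monthly climate to the fine grid:
## geographically weighted regression (GWR) of the coarse response on coarse
## elevation, ordinary kriging of the local coefficient surfaces to the fine
## grid, prediction from fine elevation, and a kriged-residual station
## correction. All machinery is shared by temperature and precipitation.

#' Geographically weighted regression on elevation
#'
#' At every coarse cell, weighted least squares of the response on elevation
#' with Gaussian kernel weights \code{w = exp(-0.5 (d / bandwidth)^2)} over
#' all coarse cells. A locally singular design (constant elevation within
#' the kernel) falls back to the local weighted mean with zero slope and is
#' flagged.
#'
#' @param response coarse \code{river_grid} (e.g. one month of tmin).
#' @param predictor_elev coarse elevation \code{river_grid}, aligned.
#' @param bandwidth Gaussian kernel bandwidth, metres.
#' @return a \code{gwr_fit}: data.frame(x, y, intercept, slope, flagged) plus
#'   the bandwidth.
#' @export
gwr_fit <- function(response, predictor_elev, bandwidth) {
  stopifnot_same_geometry(response, predictor_elev)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  ok <- which(!is.na(response$values) & !is.na(predictor_elev$values))
  xy <- grid_xy(response, ok)
  y <- response$values[ok]; e <- predictor_elev$values[ok]
  n <- length(ok)
  intercept <- slope <- numeric(n); flagged <- logical(n)
  for (i in seq_len(n)) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    w <- exp(-0.5 * d2 / bandwidth^2)
    sw <- sum(w)
    if (sum(w > 1e-12) < 3L)
      stop("fewer than 3 cells carry weight within the bandwidth")
    ebar <- sum(w * e) / sw; ybar <- sum(w * y) / sw
    sxx <- sum(w * (e - ebar)^2)
    if (sxx < 1e-10 * sw) {             # constant elevation in window
      intercept[i] <- ybar; slope[i] <- 0; flagged[i] <- TRUE
    } else {
      b <- sum(w * (e - ebar) * (y - ybar)) / sxx
      slope[i] <- b; intercept[i] <- ybar - b * ebar
    }
  }
  structure(list(coef = data.frame(x = xy[, 1], y = xy[, 2], elev = e,
                                   intercept = intercept, slope = slope,
                                   flagged = flagged),
                 bandwidth = bandwidth),
            class = "gwr_fit")
}

#' Bandwidth selection by leave-one-out cross-validation
#'
#' For each candidate, every coarse cell is predicted from a local fit with
#' its own weight removed; the candidate minimizing the mean squared LOO
#' error wins. Equal scores break to the smallest bandwidth.
#'
#' @param response,predictor_elev aligned coarse \code{river_grid}s.
#' @param candidates numeric vector of candidate bandwidths, metres.
#' @return the selected bandwidth.
#' @export
select_bandwidth <- function(response, predictor_elev, candidates) {
  if (length(candidates) < 1L) stop("no candidate bandwidths supplied")
  if (length(candidates) == 1L) return(candidates)
  stopifnot_same_geometry(response, predictor_elev)
  ok <- which(!is.na(response$values) & !is.na(predictor_elev$values))
  xy <- grid_xy(response, ok)
  y <- response$values[ok]; e <- predictor_elev$values[ok]
  n <- length(ok)
  d2m <- outer(xy[, 1], xy[, 1], "-")^2 + outer(xy[, 2], xy[, 2], "-")^2
  score <- vapply(candidates, function(bw) {
    err <- vapply(seq_len(n), function(i) {
      w <- exp(-0.5 * d2m[i, ] / bw^2)
      w[i] <- 0
      sw <- sum(w)
      if (sw <= 0) return(NA_real_)
      ebar <- sum(w * e) / sw; ybar <- sum(w * y) / sw
      sxx <- sum(w * (e - ebar)^2)
      pred <- if (sxx < 1e-10 * sw) ybar
              else ybar + sum(w * (e - ebar) * (y - ybar)) / sxx * (e[i] - ebar)
      (y[i] - pred)^2
    }, numeric(1))
    mean(err, na.rm = TRUE)
  }, numeric(1))
  o <- order(candidates)
  cand <- candidates[o]; score <- score[o]
  ## scores within a sliver of the minimum count as ties (an exactly linear
  ## field gives CV errors at floating noise for every bandwidth); ties go
  ## to the smallest bandwidth
  tol <- 1e-9 * max(stats::var(y), .Machine$double.xmin)
  cand[which(score <= min(score) + tol)[1L]]
}

vg_gamma <- function(model, h) {
  n <- model$nugget; s <- model$psill; a <- model$range
  g <- switch(model$family,
    spherical = ifelse(h >= a, n + s,
                       n + s * (1.5 * h / a - 0.5 * (h / a)^3)),
    exponential = n + s * (1 - exp(-3 * h / a)),
    gaussian = n + s * (1 - exp(-3 * (h / a)^2)))
  g[h == 0] <- 0      # gamma(0) = 0 by definition (nugget is the jump)
  g
}

#' Fit a variogram model automatically
#'
#' Empirical semivariance in 12 equal-width distance bins up to half the
#' largest pair distance; spherical, exponential and gaussian models are fit
#' by weighted least squares (weights = pair counts) and the best SSE wins.
#'
#' @param samples data.frame with columns x, y, value (>= 10 rows).
#' @param n_bins number of distance bins (default 12).
#' @return a \code{variogram_model}: list(family, nugget, psill, range).
#' @export
fit_variogram <- function(samples, n_bins = 12L) {
  stopifnot(all(c("x", "y", "value") %in% names(samples)))
  v <- samples$value
  if (length(v) < 10L) stop("at least 10 samples are required")
  if (stats::sd(v) == 0)
    return(structure(list(family = "spherical", nugget = 0, psill = 0,
                          range = 1), class = "variogram_model"))
  d <- as.matrix(stats::dist(samples[, c("x", "y")]))
  iu <- upper.tri(d)
  h <- d[iu]
  g <- 0.5 * outer(v, v, "-")[iu]^2
  hmax <- max(h) / 2
  keep <- h <= hmax & h > 0
  h <- h[keep]; g <- g[keep]
  bins <- cut(h, breaks = seq(0, hmax, length.out = n_bins + 1L),
              include.lowest = TRUE)
  hb <- tapply(h, bins, mean)
  gb <- tapply(g, bins, mean)
  wb <- tapply(g, bins, length)
  ok <- !is.na(gb)
  hb <- hb[ok]; gb <- gb[ok]; wb <- wb[ok]
  svar <- stats::var(v)
  fit_family <- function(family) {
    obj <- function(p) {
      m <- list(family = family, nugget = p[1], psill = p[2], range = p[3])
      sum(wb * (gb - vg_gamma(m, hb))^2)
    }
    start <- c(nugget = max(min(gb), 1e-8), psill = max(svar - min(gb), 1e-8),
               range = hmax / 2)
    o <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 0, hmax * 1e-3),
                      upper = c(Inf, Inf, hmax * 10))
    list(par = o$par, sse = o$value)
  }
  fams <- c("spherical", "exponential", "gaussian")
  fits <- lapply(fams, fit_family)
  best <- which.min(vapply(fits, `[[`, numeric(1), "sse"))
  p <- fits[[best]]$par
  structure(list(family = fams[best], nugget = unname(p[1]),
                 psill = unname(p[2]), range = unname(p[3])),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, psill %.4g, range %.4g\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

## solve the ordinary kriging system for samples -> target coordinates;
## returns list(pred, weights) where weights is n_samples x n_targets
krige_solve <- function(sx, sy, sv, model, tx, ty, return_weights = FALSE) {
  n <- length(sv)
  D <- as.matrix(stats::dist(cbind(sx, sy)))
  K <- rbind(cbind(vg_gamma(model, D), 1), c(rep(1, n), 0))
  dt <- sqrt(outer(sx, tx, "-")^2 + outer(sy, ty, "-")^2)
  rhs <- rbind(vg_gamma(model, dt), 1)
  sol <- tryCatch(solve(K, rhs), error = function(e) {
    solve(K + diag(c(rep(1e-9 * max(1, max(K)), n), 0)), rhs)
  })
  w <- sol[seq_len(n), , drop = FALSE]
  pred <- drop(crossprod(w, sv))
  if (return_weights) list(pred = pred, weights = w) else list(pred = pred)
}

#' Ordinary kriging onto a grid
#'
#' Best linear unbiased prediction under the fitted variogram with the
#' unbiasedness constraint (weights sum to 1); exact at sample locations.
#' Duplicate sample coordinates are averaged with a warning. A pure-nugget
#' zero-sill model degenerates to the sample mean.
#'
#' @param samples data.frame(x, y, value).
#' @param variogram a \code{variogram_model}.
#' @param target a \code{river_grid} defining the prediction geometry, or a
#'   data.frame/matrix of x, y coordinates.
#' @return a \code{river_grid} (grid target) or numeric vector (coordinates).
#' @export
krige_surface <- function(samples, variogram, target) {
  stopifnot(inherits(variogram, "variogram_model"))
  if (nrow(samples) < 3L) stop("at least 3 samples are required")
  key <- paste(samples$x, samples$y)
  if (anyDuplicated(key)) {
    warning("duplicate sample coordinates averaged before kriging")
    samples <- stats::aggregate(value ~ x + y, samples, mean)
  }
  grid_out <- inherits(target, "river_grid")
  if (grid_out) {
    idx <- seq_along(target$values)
    xy <- grid_xy(target, idx)
  } else xy <- cbind(x = target[, 1], y = target[, 2])
  if (variogram$nugget + variogram$psill <= 0) {
    pred <- rep(mean(samples$value), nrow(xy))
  } else {
    pred <- krige_solve(samples$x, samples$y, samples$value, variogram,
                        xy[, 1], xy[, 2])$pred
  }
  if (grid_out)
    river_grid(matrix(pred, nrow(target$values), ncol(target$values)),
               target$cell_size, target$origin)
  else unname(pred)
}

#' Station-based residual correction
#'
#' Residuals (station value minus downscaled value at the station cell) are
#' kriged over the grid and added, so the corrected surface matches the
#' stations exactly at their cells. Stations outside the grid are dropped
#' with a warning; with fewer than 10 stations the residual variogram falls
#' back to an exponential model with range one quarter of the domain
#' diagonal and sill equal to the residual variance.
#'
#' @param downscaled fine \code{river_grid}.
#' @param stations data.frame(x, y, value) of point observations.
#' @return corrected \code{river_grid}.
#' @export
station_correction <- function(downscaled, stations) {
  if (nrow(stations) < 3L) stop("at least 3 stations are required")
  cell <- grid_cell_at(downscaled, stations$x, stations$y)
  if (anyNA(cell)) {
    warning(sum(is.na(cell)), " station(s) outside the grid dropped")
    stations <- stations[!is.na(cell), ]
    cell <- cell[!is.na(cell)]
  }
  ## snap to cell centres so kriging exactness lands on the station cells
  xy <- grid_xy(downscaled, cell)
  res <- stations$value - downscaled$values[cell]
  samp <- data.frame(x = xy[, 1], y = xy[, 2], value = res)
  if (stats::sd(res) == 0) {
    out <- downscaled
    out$values <- out$values + res[1]
    return(out)
  }
  vg <- if (nrow(samp) >= 10L) fit_variogram(samp) else {
    nr <- nrow(downscaled$values); nc <- ncol(downscaled$values)
    diag_m <- downscaled$cell_size * sqrt(nr^2 + nc^2)
    structure(list(family = "exponential", nugget = 0,
                   psill = stats::var(res), range = diag_m / 4),
              class = "variogram_model")
  }
  corr <- krige_surface(samp, vg, downscaled)
  out <- downscaled
  out$values <- out$values + corr$values
  out
}

#' Predict the fine surface from kriged GWR coefficients
#'
#' @param intercept_surface,slope_surface fine \code{river_grid}s of the
#'   kriged local intercept and slope.
#' @param fine_dem fine elevation \code{river_grid}, aligned.
#' @param floor_zero clamp negative predictions to 0 (precipitation).
#' @return fine \code{river_grid}.
#' @export
downscale_predict <- function(intercept_surface, slope_surface, fine_dem,
                              floor_zero = FALSE) {
  stopifnot_same_geometry(intercept_surface, fine_dem)
  stopifnot_same_geometry(slope_surface, fine_dem)
  v <- intercept_surface$values + slope_surface$values * fine_dem$values
  if (floor_zero) v <- pmax(v, 0)
  river_grid(v, fine_dem$cell_size, fine_dem$origin)
}

#' Downscale one coarse surface to the fine grid
#'
#' GWR on coarse elevation, ordinary kriging of the local coefficient
#' surfaces (automatic variogram each), prediction from fine elevation, then
#' optional station correction.
#'
#' @param response coarse \code{river_grid}.
#' @param dem_coarse,dem_fine elevation grids at the two resolutions.
#' @param bandwidth GWR bandwidth in metres; NULL selects by LOO-CV over
#'   \code{c(2, 4, 8) * coarse cell size}.
#' @param stations optional data.frame(x, y, value) for residual correction.
#' @param floor_zero clamp negatives (precipitation).
#' @return fine \code{river_grid}.
#' @export
downscale_surface <- function(response, dem_coarse, dem_fine,
                              bandwidth = NULL, stations = NULL,
                              floor_zero = FALSE) {
  if (is.null(bandwidth))
    bandwidth <- select_bandwidth(response, dem_coarse,
                                  c(2, 4, 8) * response$cell_size)
  fit <- gwr_fit(response, dem_coarse, bandwidth)
  co <- fit$coef
  krige_coef <- function(col) {
    samp <- data.frame(x = co$x, y = co$y, value = co[[col]])
    vg <- fit_variogram(samp)
    krige_surface(samp, vg, dem_fine)
  }
  a <- krige_coef("intercept")
  b <- krige_coef("slope")
  out <- downscale_predict(a, b, dem_fine, floor_zero = floor_zero)
  if (!is.null(stations) && nrow(stations) >= 3L)
    out <- station_correction(out, stations)
  if (floor_zero) out$values <- pmax(out$values, 0)
  out
}

#' Downscale a full monthly climate stack
#'
#' 36 independent surface downscalings (12 months x tmin/tmax/prcp) sharing
#' one LOO-CV bandwidth per variable, with station correction where station
#' records are supplied. After the independent tmin/tmax downscalings, any
#' cell-month with tmax < tmin is repaired to the midpoint +/- 0.1 degC and
#' counted in the \code{repaired} attribute.
#'
#' @param coarse a coarse \code{monthly_climate}.
#' @param dem_coarse,dem_fine elevation grids.
#' @param stations long-format station table (station_id, x, y, variable,
#'   month, value) as produced by \code{\link{make_monthly_climate}}, or NULL.
#' @param bandwidth fixed GWR bandwidth, or NULL for LOO-CV on January of
#'   each variable.
#' @return a fine \code{monthly_climate} with attribute \code{repaired}.
#' @export
downscale_climate <- function(coarse, dem_coarse, dem_fine, stations = NULL,
                              bandwidth = NULL) {
  stopifnot(inherits(coarse, "monthly_climate"))
  nr <- nrow(dem_fine$values); nc <- ncol(dem_fine$values)
  out <- list()
  for (var in c("tmin", "tmax", "prcp")) {
    floor0 <- var == "prcp"
    bw <- bandwidth
    if (is.null(bw))
      bw <- select_bandwidth(climate_layer(coarse, var, 1L), dem_coarse,
                             c(2, 4, 8) * coarse$cell_size)
    arr <- array(NA_real_, c(nr, nc, 12))
    for (m in 1:12) {
      st <- NULL
      if (!is.null(stations)) {
        st <- stations[stations$variable == var & stations$month == m,
                       c("x", "y", "value")]
        if (nrow(st) < 3L) st <- NULL
      }
      g <- downscale_surface(climate_layer(coarse, var, m), dem_coarse,
                             dem_fine, bandwidth = bw, stations = st,
                             floor_zero = floor0)
      arr[, , m] <- g$values
    }
    out[[var]] <- arr
  }
  bad <- out$tmax < out$tmin
  if (any(bad)) {
    mid <- (out$tmax[bad] + out$tmin[bad]) / 2
    out$tmax[bad] <- mid + 0.1
    out$tmin[bad] <- mid - 0.1
  }
  res <- monthly_climate(out$tmin, out$tmax, out$prcp, dem_fine$cell_size,
                         dem_fine$origin, "fine")
  attr(res, "repaired") <- sum(bad)
  res
}
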