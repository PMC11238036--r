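#' Configuration of a synthetic riverscape world
#'
#' The synthetic world stands in for the real study inputs (a 30 m DEM, coarse
#' gridded monthly climate, gauge-station records, occurrence downloads): a
#' drainable elevation grid, monthly tmin/tmax/precipitation surfaces with an
#' elevation lapse and a seasonal cycle at fine and coarse resolution, point
#' "station" samples, and presences drawn from a known niche. Every generator
#' is a pure function of (config, seed); the master seed expands to fixed
#' per-stage substreams (see \code{stage_seed}).
#'
#' @param grid_rows,grid_cols fine-grid dimensions (>= 16).
#' @param cell_size fine cell edge, metres.
#' @param seed master integer seed.
#' @param relief_amplitude metres; ~2 standard deviations of the smoothed
#'   random relief field.
#' @param regional_slope dimensionless regional tilt (metres per metre),
#'   rising eastward so drainage runs to the western boundary.
#' @param lapse_rate temperature lapse, degrees C per km of elevation.
#' @param seasonal_temp_amplitude degrees C; half-range of the sea-level
#'   seasonal sinusoid (southern-hemisphere phase, January warmest).
#' @param annual_precip_base mm/yr at sea level.
#' @param precip_orographic_factor mm/yr of extra precipitation per km of
#'   elevation.
#' @param station_count number of synthetic gauge stations (>= 10).
#' @param coarse_factor integer aggregation ratio fine -> coarse; must divide
#'   both grid dimensions.
#' @param temp_noise_sd per-cell Gaussian noise on monthly temperatures, deg C.
#' @param precip_noise_cv per-cell multiplicative precipitation noise
#'   (coefficient of variation).
#' @return a \code{synth_world_config} list.
#' @export
world_config <- function(grid_rows = 64L, grid_cols = 64L, cell_size = 100,
                         seed = 1L, relief_amplitude = 150,
                         regional_slope = 0.2, lapse_rate = 6.5,
                         seasonal_temp_amplitude = 6,
                         annual_precip_base = 1200,
                         precip_orographic_factor = 800,
                         station_count = 15L, coarse_factor = 4L,
                         temp_noise_sd = 0.3, precip_noise_cv = 0.05) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              cell_size = cell_size, seed = as.integer(seed),
              relief_amplitude = relief_amplitude,
              regional_slope = regional_slope, lapse_rate = lapse_rate,
              seasonal_temp_amplitude = seasonal_temp_amplitude,
              annual_precip_base = annual_precip_base,
              precip_orographic_factor = precip_orographic_factor,
              station_count = as.integer(station_count),
              coarse_factor = as.integer(coarse_factor),
              temp_noise_sd = temp_noise_sd,
              precip_noise_cv = precip_noise_cv)
  if (cfg$grid_rows < 16L || cfg$grid_cols < 16L)
    stop("grid dimensions must be at least 16 x 16")
  if (cfg$cell_size <= 0) stop("cell_size must be positive")
  if (cfg$grid_rows %% cfg$coarse_factor != 0L ||
      cfg$grid_cols %% cfg$coarse_factor != 0L)
    stop("coarse_factor must divide both grid dimensions")
  if (cfg$station_count < 10L) stop("station_count must be at least 10")
  class(cfg) <- "synth_world_config"
  cfg
}

#' Per-stage substream of a master seed
#'
#' Fixed offsets keep the stages independently reproducible: dem = 11,
#' climate = 23, stations = 37, presences = 53. Result stays below 2^31.
#'
#' @param seed master seed.
#' @param stage one of "dem", "climate", "stations", "presences".
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage = c("dem", "climate", "stations",
                                       "presences")) {
  stage <- match.arg(stage)
  off <- c(dem = 11, climate = 23, stations = 37, presences = 53)[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

## separable Gaussian blur with replicated edges; sigma in cells
gaussian_smooth <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_filter <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], half), x, rep(x[n], half))
    stats::filter(xp, k, sides = 2)[(half + 1):(half + n)]
  }
  m <- apply(m, 2, pad_filter)
  t(apply(m, 1, pad_filter))
}

#' Generate a drainable synthetic DEM
#'
#' Elevation = regional tilt rising eastward + Gaussian-smoothed white noise
#' (smoothing length ~ 8 cells) scaled so that relief_amplitude is about two
#' standard deviations, shifted to a non-negative minimum. The western
#' boundary is the low (ocean-facing) edge.
#'
#' @param config a \code{synth_world_config}.
#' @return an \code{ElevationGrid} (\code{river_grid}) in metres.
#' @export
make_dem <- function(config) {
  stopifnot(inherits(config, "synth_world_config"))
  nr <- config$grid_rows; nc <- config$grid_cols; cs <- config$cell_size
  set.seed(stage_seed(config$seed, "dem"))
  plane <- matrix(rep((seq_len(nc) - 1) * cs * config$regional_slope,
                      each = nr), nr, nc)
  if (config$relief_amplitude > 0) {
    noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    sm <- gaussian_smooth(noise, sigma = 8)
    sm <- (sm - mean(sm)) / stats::sd(sm)
    relief <- sm * config$relief_amplitude / 2
  } else relief <- 0
  z <- plane + relief
  z <- z - min(z)
  river_grid(z, cs)
}

#' Monthly climate stack
#'
#' Container for 12 monthly grids each of tmin, tmax (deg C) and prcp (mm),
#' stored as nrow x ncol x 12 arrays sharing one placement.
#'
#' @param tmin,tmax,prcp numeric arrays, dim c(nr, nc, 12).
#' @param cell_size,origin placement (see \code{\link{river_grid}}).
#' @param resolution tag, "fine" or "coarse".
#' @return a \code{monthly_climate} object.
#' @export
monthly_climate <- function(tmin, tmax, prcp, cell_size, origin = c(0, 0),
                            resolution = "fine") {
  for (a in list(tmin, tmax, prcp))
    if (length(dim(a)) != 3L || dim(a)[3] != 12L)
      stop("climate layers must be nr x nc x 12 arrays")
  if (any(tmax < tmin, na.rm = TRUE))
    stop("tmax must be >= tmin at every cell and month")
  if (any(prcp < 0, na.rm = TRUE)) stop("precipitation must be non-negative")
  structure(list(tmin = tmin, tmax = tmax, prcp = prcp,
                 cell_size = cell_size, origin = as.numeric(origin),
                 resolution = resolution),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  d <- dim(x$tmin)
  cat(sprintf("<monthly_climate> %s, %d x %d x 12, cell %g m\n",
              x$resolution, d[1], d[2], x$cell_size))
  invisible(x)
}

## extract month layer as river_grid
climate_layer <- function(clim, var, month) {
  river_grid(clim[[var]][, , month], clim$cell_size, clim$origin)
}

#' Generate synthetic monthly climate at fine and coarse resolution
#'
#' Sea-level mean temperature follows a seasonal sinusoid (January warmest,
#' southern hemisphere) with a fixed 10 degree diurnal tmax-tmin gap; the
#' lapse term subtracts \code{lapse_rate} x elevation(km); independent
#' per-cell Gaussian noise (sd \code{temp_noise_sd}) is added per month.
#' Monthly precipitation is winter-peaked (July maximum) with an orographic
#' term proportional to elevation and multiplicative noise of coefficient of
#' variation \code{precip_noise_cv}, floored at 0. The coarse stack is the
#' block-mean aggregation of the fine stack by \code{coarse_factor}; stations
#' are exact fine-grid values at \code{station_count} distinct random cells.
#'
#' @param dem fine-resolution \code{river_grid} from \code{\link{make_dem}}.
#' @param config the \code{synth_world_config} used for the DEM.
#' @return list with elements \code{fine}, \code{coarse}
#'   (\code{monthly_climate}), \code{dem_coarse} (\code{river_grid}) and
#'   \code{stations} (data.frame station_id, x, y, variable, month, value).
#' @export
make_monthly_climate <- function(dem, config) {
  stopifnot(inherits(dem, "river_grid"), inherits(config, "synth_world_config"))
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  set.seed(stage_seed(config$seed, "climate"))
  months <- 1:12
  tmean_sea <- 14 + config$seasonal_temp_amplitude * cospi(2 * (months - 1) / 12)
  prcp_season <- (1 + 0.8 * cospi(2 * (months - 7) / 12))
  prcp_season <- prcp_season / sum(prcp_season)   # monthly shares, sum 1
  elev_km <- dem$values / 1000
  tmin <- tmax <- prcp <- array(NA_real_, c(nr, nc, 12))
  for (m in months) {
    base <- tmean_sea[m] - config$lapse_rate * elev_km
    tmin[, , m] <- base - 5 + stats::rnorm(nr * nc, sd = config$temp_noise_sd)
    tmax[, , m] <- base + 5 + stats::rnorm(nr * nc, sd = config$temp_noise_sd)
    p <- (config$annual_precip_base +
            config$precip_orographic_factor * elev_km) * prcp_season[m]
    p <- p * (1 + config$precip_noise_cv * stats::rnorm(nr * nc))
    prcp[, , m] <- pmax(p, 0)
  }
  ## enforce the physical ordering in the (never observed at sd 0.3 with a
  ## 10 degree gap) event that noise crosses the two series
  bad <- tmax < tmin
  if (any(bad)) { mid <- (tmax[bad] + tmin[bad]) / 2
    tmax[bad] <- mid + 0.1; tmin[bad] <- mid - 0.1 }
  fine <- monthly_climate(tmin, tmax, prcp, dem$cell_size, dem$origin, "fine")
  coarse <- aggregate_climate(fine, config$coarse_factor)
  dem_coarse <- aggregate_grid(dem, config$coarse_factor)
  set.seed(stage_seed(config$seed, "stations"))
  cells <- sample.int(nr * nc, config$station_count)
  xy <- grid_xy(dem, cells)
  stations <- do.call(rbind, lapply(c("tmin", "tmax", "prcp"), function(v) {
    do.call(rbind, lapply(months, function(m) {
      data.frame(station_id = seq_along(cells), x = xy[, "x"], y = xy[, "y"],
                 variable = v, month = m,
                 value = fine[[v]][, , m][cells])
    }))
  }))
  rownames(stations) <- NULL
  list(fine = fine, coarse = coarse, dem_coarse = dem_coarse,
       stations = stations)
}

#' Block-mean aggregation of a climate stack
#' @param clim a \code{monthly_climate}.
#' @param factor integer aggregation ratio.
#' @return a coarse \code{monthly_climate}.
#' @export
aggregate_climate <- function(clim, factor) {
  agg <- function(a) {
    out <- NULL
    for (m in 1:12) {
      g <- aggregate_grid(river_grid(a[, , m], clim$cell_size, clim$origin),
                          factor)
      if (is.null(out)) out <- array(NA_real_, c(dim(g$values), 12))
      out[, , m] <- g$values
    }
    out
  }
  monthly_climate(agg(clim$tmin), agg(clim$tmax), agg(clim$prcp),
                  clim$cell_size * factor, clim$origin, "coarse")
}

#' Climate-change scenario as parametric deltas
#'
#' Stand-in for GCM future layers: a spatially constant additive temperature
#' shift and multiplicative precipitation scaling (SSP245-like, SSP585-like).
#'
#' @param delta_t degrees C added to all monthly temperatures.
#' @param precip_scale multiplier on all monthly precipitation (> 0).
#' @param label scenario label.
#' @return a \code{scenario_delta} object.
#' @export
scenario_delta <- function(delta_t, precip_scale, label = "scenario") {
  if (precip_scale <= 0) stop("precip_scale must be positive")
  structure(list(delta_t = delta_t, precip_scale = precip_scale,
                 label = label), class = "scenario_delta")
}

#' Apply a scenario delta to a climate stack
#' @param climate a \code{monthly_climate}.
#' @param delta a \code{scenario_delta}.
#' @return the transformed \code{monthly_climate}.
#' @export
apply_scenario <- function(climate, delta) {
  stopifnot(inherits(climate, "monthly_climate"),
            inherits(delta, "scenario_delta"))
  monthly_climate(climate$tmin + delta$delta_t, climate$tmax + delta$delta_t,
                  climate$prcp * delta$precip_scale, climate$cell_size,
                  climate$origin, climate$resolution)
}

#' Known ("true") niche over derived predictors
#'
#' Ground truth for parameter-recovery tests: suitability is the inverse
#' logit of \code{baseline - sum_k weight_k ((x_k - optimum_k)/breadth_k)^2},
#' a product-Gaussian-like niche on the logit scale.
#'
#' @param responses data.frame with columns predictor, optimum, breadth (> 0),
#'   weight.
#' @param baseline logit-scale intercept (suitability at all optima is
#'   \code{plogis(baseline)}).
#' @return a \code{true_niche} object.
#' @export
true_niche <- function(responses, baseline = 0) {
  stopifnot(is.data.frame(responses),
            all(c("predictor", "optimum", "breadth", "weight") %in%
                  names(responses)))
  if (nrow(responses) < 1L) stop("at least one predictor response is required")
  if (any(responses$breadth <= 0)) stop("breadth must be positive")
  structure(list(responses = responses, baseline = baseline),
            class = "true_niche")
}

#' Evaluate the true niche on a predictor table
#' @param predictors data.frame of per-reach predictors.
#' @param niche a \code{true_niche}.
#' @return suitability in [0, 1], one value per row.
#' @export
true_suitability <- function(predictors, niche) {
  stopifnot(inherits(niche, "true_niche"))
  miss <- setdiff(niche$responses$predictor, names(predictors))
  if (length(miss))
    stop("predictor(s) missing from table: ", paste(miss, collapse = ", "))
  lp <- rep(niche$baseline, nrow(predictors))
  for (i in seq_len(nrow(niche$responses))) {
    r <- niche$responses[i, ]
    lp <- lp - r$weight * ((predictors[[r$predictor]] - r$optimum) /
                             r$breadth)^2
  }
  stats::plogis(lp)
}

#' Sample presence records from per-reach suitability
#'
#' Reaches are drawn without replacement with probability proportional to
#' suitability (one record per reach, mimicking filtered occurrence data);
#' the occurrence coordinate is the reach midpoint.
#'
#' @param network a \code{stream_network}.
#' @param suitability per-reach probabilities aligned with
#'   \code{network$reaches}.
#' @param n number of presences.
#' @param seed integer seed.
#' @return data.frame (reach_id, x, y).
#' @export
sample_presences <- function(network, suitability, n, seed) {
  stopifnot(n >= 1)
  pos <- which(suitability > 0)
  if (length(pos) == 0L) stop("no reach has positive suitability")
  if (n > length(pos))
    stop("n exceeds the number of positive-suitability reaches (",
         length(pos), ")")
  set.seed(as.integer(seed))
  take <- pos[sample.int(length(pos), n, prob = suitability[pos])]
  data.frame(reach_id = network$reaches$reach_id[take],
             x = network$reaches$mid_x[take],
             y = network$reaches$mid_y[take])
}
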