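## The 19 standard bioclimatic variables plus the 8 catchment-averaged
## "hydroclimatic" precipitation variants attached per stream reach.
## Conventions stated explicitly because implementations differ:
##   * bio4 is the population (n-denominator) sd of monthly mean temperature
##     x 100; bio15 uses the ANUCLIM adjustment 100 * sd(prcp)/(1 + bio12/12).
##   * quarters are all 12 wrap-around 3-month windows (Dec-Jan-Feb included);
##     ties between windows break to the earliest window.

pop_sd <- function(x) sqrt(rowMeans((x - rowMeans(x))^2))

## rolling wrap-around 3-month window sums, n x 12 in -> n x 12 out
quarter_sum <- function(m) {
  m[, 1:12, drop = FALSE] + m[, c(2:12, 1), drop = FALSE] +
    m[, c(3:12, 1:2), drop = FALSE]
}

#' Derive the 19 bioclimatic variables
#'
#' Standard definitions from 12 monthly values of minimum temperature,
#' maximum temperature and precipitation. Accepts length-12 vectors (one
#' site) or n x 12 matrices (one row per site).
#'
#' @param tmin,tmax monthly temperatures, deg C.
#' @param prcp monthly precipitation, mm.
#' @return data.frame with columns bio1..bio19 (one row per site); a named
#'   vector if the inputs were vectors.
#' @export
bioclim19 <- function(tmin, tmax, prcp) {
  vec_in <- is.null(dim(tmin))
  as_m <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  tmin <- as_m(tmin); tmax <- as_m(tmax); prcp <- as_m(prcp)
  if (ncol(tmin) != 12L || ncol(tmax) != 12L || ncol(prcp) != 12L)
    stop("each monthly series must have 12 values")
  if (any(tmax < tmin)) stop("tmax must be >= tmin in every month")
  n <- nrow(tmin)
  tmean <- (tmin + tmax) / 2
  qt <- quarter_sum(tmean) / 3      # quarter mean temperature
  qp <- quarter_sum(prcp)           # quarter precipitation totals
  pick <- function(q, which = c("max", "min")) {
    ## earliest window on ties: max.col(ties.method = "first")
    if (match.arg(which) == "max") max.col(q, ties.method = "first")
    else max.col(-q, ties.method = "first")
  }
  wet <- pick(qp, "max"); dry <- pick(qp, "min")
  warm <- pick(qt, "max"); cold <- pick(qt, "min")
  at <- function(m, j) m[cbind(seq_len(n), j)]
  b1 <- rowMeans(tmean)
  b2 <- rowMeans(tmax - tmin)
  b5 <- apply(tmax, 1, max)
  b6 <- apply(tmin, 1, min)
  b7 <- b5 - b6
  b3 <- ifelse(b7 == 0, 0, b2 / b7 * 100)
  b4 <- pop_sd(tmean) * 100
  b12 <- rowSums(prcp)
  out <- data.frame(
    bio1 = b1, bio2 = b2, bio3 = b3, bio4 = b4, bio5 = b5, bio6 = b6,
    bio7 = b7,
    bio8 = at(qt, wet), bio9 = at(qt, dry),
    bio10 = at(qt, warm), bio11 = at(qt, cold),
    bio12 = b12,
    bio13 = apply(prcp, 1, max), bio14 = apply(prcp, 1, min),
    bio15 = 100 * pop_sd(prcp) / (1 + b12 / 12),
    bio16 = at(qp, wet), bio17 = at(qp, dry),
    bio18 = at(qp, warm), bio19 = at(qp, cold))
  if (vec_in) unlist(out[1, ]) else out
}

#' Mean of a grid over a catchment
#'
#' @param grid a \code{river_grid}.
#' @param cells integer cell indices of the catchment.
#' @return arithmetic mean over the catchment, NAs excluded.
#' @export
catchment_mean <- function(grid, cells) {
  if (length(cells) == 0L) stop("empty catchment")
  v <- grid$values[cells]
  if (all(is.na(v))) stop("catchment contains only nodata cells")
  mean(v, na.rm = TRUE)
}

#' Catchment-averaged monthly precipitation series per reach
#'
#' @param prcp nr x nc x 12 precipitation array (fine grid).
#' @param catchments list of cell-index vectors (\code{\link{catchment_sets}}).
#' @return n_reach x 12 matrix of catchment-mean precipitation, mm.
#' @export
catchment_prcp_series <- function(prcp, catchments) {
  n <- length(catchments)
  out <- matrix(NA_real_, n, 12)
  flat <- matrix(prcp, ncol = 12)   # cells x months view
  for (i in seq_len(n)) {
    v <- flat[catchments[[i]], , drop = FALSE]
    out[i, ] <- colMeans(v, na.rm = TRUE)
  }
  if (anyNA(out)) stop("catchment with only nodata precipitation")
  out
}

#' The 8 hydroclimatic variables (bio12h-bio19h)
#'
#' The precipitation-associated bioclim variables bio12-bio19 recomputed
#' from the catchment-averaged monthly precipitation series of each reach,
#' proxying discharge conditions. Wettest/driest quarters are selected on
#' the catchment-averaged series itself; warmest/coldest quarters use the
#' reach-local temperatures.
#'
#' @param catchment_prcp n x 12 matrix from
#'   \code{\link{catchment_prcp_series}}.
#' @param tmin,tmax n x 12 matrices of reach-local monthly temperatures.
#' @return data.frame bio12h..bio19h, one row per reach.
#' @export
hydroclim8 <- function(catchment_prcp, tmin, tmax) {
  full <- bioclim19(tmin, tmax, catchment_prcp)
  out <- full[, paste0("bio", 12:19)]
  names(out) <- paste0("bio", 12:19, "h")
  out
}

#' Per-reach predictor table
#'
#' The single modelling input: geophysical reach attributes plus bio1-bio19
#' at the reach midpoint cell and the catchment-averaged bio12h-bio19h.
#'
#' @param network a characterized \code{stream_network}.
#' @param climate a fine \code{monthly_climate} aligned with the network DEM.
#' @param catchments optional precomputed \code{\link{catchment_sets}} list.
#' @return data.frame keyed by reach_id.
#' @export
reach_predictors <- function(network, climate, catchments = NULL) {
  r <- network$reaches
  ref <- river_grid(matrix(0, dim(climate$tmin)[1], dim(climate$tmin)[2]),
                    climate$cell_size, climate$origin)
  mid <- grid_cell_at(ref, r$mid_x, r$mid_y)
  pull <- function(a) {
    flat <- matrix(a, ncol = 12)
    flat[mid, , drop = FALSE]
  }
  tmin <- pull(climate$tmin); tmax <- pull(climate$tmax)
  prcp <- pull(climate$prcp)
  bio <- bioclim19(tmin, tmax, prcp)
  if (is.null(catchments)) catchments <- catchment_sets(network)
  cp <- catchment_prcp_series(climate$prcp, catchments)
  hyd <- hydroclim8(cp, tmin, tmax)
  cbind(r[, c("reach_id", "length_m", "elevation", "gradient", "sinuosity",
              "aspect", "strahler", "valley_confinement", "drainage_area",
              "dist_downstream", "dist_upstream")],
        bio, hyd)
}
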