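## Suitability -> three-class habitat maps, stream-length tallies,
## present-vs-future change accounting, and kernel-density summaries.
##
## Class boundary convention (stated prominently because the source figure
## captions and methods text disagree): unsuitable P < MTP, moderate
## MTP <= P < 0.5, high P >= 0.5.

HABITAT_CLASSES <- c("unsuitable", "moderate", "high")

#' Minimum training presence (MTP) threshold
#'
#' @param training_suitability suitability of the training presences.
#' @return the minimum training suitability.
#' @export
mtp_threshold <- function(training_suitability) {
  if (length(training_suitability) < 1L) stop("no training presences")
  min(training_suitability)
}

#' Classify suitability into three habitat classes
#'
#' @param p per-reach suitability in [0, 1].
#' @param mtp minimum-training-presence threshold, must lie in (0, 0.5).
#' @return factor with levels unsuitable, moderate, high.
#' @export
classify_suitability <- function(p, mtp) {
  if (mtp <= 0 || mtp >= 0.5) stop("mtp must lie in (0, 0.5)")
  cl <- ifelse(p >= 0.5, "high", ifelse(p >= mtp, "moderate", "unsuitable"))
  factor(cl, levels = HABITAT_CLASSES)
}

#' Stream length per habitat class
#'
#' @param classes factor from \code{\link{classify_suitability}}.
#' @param lengths_m reach lengths, metres (or a count of 15 m pixels times
#'   15 when mirroring a pixel-based tally).
#' @return named vector: km per class plus \code{suitable} (moderate+high).
#' @export
suitable_length_km <- function(classes, lengths_m) {
  if (length(classes) != length(lengths_m))
    stop("classes and lengths differ in length")
  km <- vapply(HABITAT_CLASSES, function(cl)
    sum(lengths_m[classes == cl]) / 1000, numeric(1))
  c(km, suitable = unname(km["moderate"] + km["high"]))
}

#' Present-vs-future habitat change accounting
#'
#' Per reach, "suitable" means class moderate or high. Stable = suitable in
#' both periods, lost = suitable only in the present, new = suitable only in
#' the future. Percentages are relative to the present-suitable total
#' (\code{denominator = "present"}, the default, under which stable + lost
#' = 100 exactly) or to the union of suitable reaches.
#'
#' @param present,future class factors over the same reach universe.
#' @param lengths_m reach lengths in metres.
#' @param denominator "present" or "union".
#' @return list: stable/lost/new km, percentages, and the per-reach change
#'   factor (levels stable, lost, new, never).
#' @export
change_analysis <- function(present, future, lengths_m,
                            denominator = c("present", "union")) {
  denominator <- match.arg(denominator)
  if (length(present) != length(future))
    stop("present and future cover different reach sets")
  ps <- present %in% c("moderate", "high")
  fs <- future %in% c("moderate", "high")
  state <- ifelse(ps & fs, "stable",
                  ifelse(ps & !fs, "lost", ifelse(fs, "new", "never")))
  state <- factor(state, levels = c("stable", "lost", "new", "never"))
  km <- function(sel) sum(lengths_m[sel]) / 1000
  stable_km <- km(state == "stable"); lost_km <- km(state == "lost")
  new_km <- km(state == "new")
  denom <- if (denominator == "present") stable_km + lost_km
           else stable_km + lost_km + new_km
  pct <- function(x) if (denom > 0) 100 * x / denom else NA_real_
  list(stable_km = stable_km, lost_km = lost_km, new_km = new_km,
       present_suitable_km = stable_km + lost_km,
       future_suitable_km = stable_km + new_km,
       stable_pct = pct(stable_km), lost_pct = pct(lost_km),
       new_pct = pct(new_km), denominator = denominator, state = state)
}

## plain Gaussian KDE evaluated on an explicit grid (kept independent of
## stats::density so the two-kernel tests can check values directly)
gaussian_kde <- function(x, bw, grid) {
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = x, sd = bw)),
                 numeric(1))
  data.frame(x = grid, density = dens)
}

#' Density of habitat suitability values
#'
#' Gaussian kernel density over per-reach suitability P with an explicit
#' bandwidth (the habitat-density figure analogue); the curve integrates to
#' 1 over the evaluation grid to quadrature tolerance.
#'
#' @param p per-reach suitability values.
#' @param bw kernel bandwidth in probability units.
#' @param grid evaluation points; defaults to 512 points spanning the data
#'   +/- 4 bandwidths.
#' @return data.frame(x, density).
#' @export
suitability_density <- function(p, bw, grid = NULL) {
  if (length(p) < 1L) stop("empty suitability map")
  if (bw <= 0) stop("bandwidth must be positive")
  if (is.null(grid))
    grid <- seq(min(p) - 4 * bw, max(p) + 4 * bw, length.out = 512L)
  gaussian_kde(p, bw, grid)
}

#' Density of suitable-reach elevations
#'
#' Gaussian KDE over the elevations of reaches whose suitability exceeds
#' the threshold (elevation-shift figure analogue).
#'
#' @param p per-reach suitability.
#' @param elevation per-reach elevations, metres.
#' @param threshold suitability cut (reaches with p > threshold included).
#' @param bw bandwidth in metres; defaults to Silverman's rule.
#' @param grid evaluation points (default 512 spanning data +/- 4 bw).
#' @return data.frame(x, density) plus attribute \code{mean_elevation};
#'   empty data.frame (with a warning) when no reach qualifies.
#' @export
elevation_density <- function(p, elevation, threshold, bw = NULL,
                              grid = NULL) {
  sel <- p > threshold
  if (!any(sel)) {
    warning("no suitable reaches above the threshold")
    out <- data.frame(x = numeric(0), density = numeric(0))
    attr(out, "mean_elevation") <- NA_real_
    return(out)
  }
  e <- elevation[sel]
  if (is.null(bw)) bw <- max(stats::bw.nrd0(e), 1e-6)
  if (is.null(grid))
    grid <- seq(min(e) - 4 * bw, max(e) + 4 * bw, length.out = 512L)
  out <- gaussian_kde(e, bw, grid)
  attr(out, "mean_elevation") <- mean(e)
  out
}
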