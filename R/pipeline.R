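## End-to-end driver: synthetic world -> stream network -> downscaling ->
## predictors -> candidate grid + selection -> present/future suitability ->
## habitat classes, change accounting and density summaries, with all
## artifacts written as plain text (ASCII grid / CSV / GeoJSON / JSON).

#' Pipeline configuration
#'
#' Bundles every stage parameter with the defaults used throughout the
#' package. The default niche is a cold/wet-optimum species: optimum annual
#' mean temperature at the cool end of the synthetic domain and optimum
#' catchment-averaged annual precipitation at the wet end, so warming/drying
#' scenarios contract habitat upslope.
#'
#' @param world a \code{\link{world_config}}.
#' @param niche a \code{\link{true_niche}}; NULL uses the default above.
#' @param n_presences presence records sampled from the true niche (150,
#'   comparable to a well-sampled occurrence download for one species).
#' @param min_area stream initiation threshold, km^2.
#' @param target_length reach length target, metres.
#' @param predictors predictor columns offered to the models.
#' @param betas,class_sets candidate grid axes.
#' @param scenarios list of \code{\link{scenario_delta}}; defaults to
#'   SSP245-like (+2 C, x0.85 precip) and SSP585-like (+4 C, x0.70 precip).
#' @param eval an \code{\link{eval_config}}.
#' @param density_bw suitability-density bandwidth.
#' @param gwr_bandwidth fixed GWR bandwidth in metres; NULL (default)
#'   selects per variable by leave-one-out cross-validation.
#' @param seed master seed (overrides \code{world$seed} and \code{eval$seed}).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(world = world_config(), niche = NULL,
                            n_presences = 150L, min_area = 0.1,
                            target_length = 100,
                            predictors = c("bio1", "bio11", "bio12",
                                           "bio12h", "strahler", "gradient"),
                            betas = c(0.5, 1, 2),
                            class_sets = list("l", "lq", "lqh"),
                            scenarios = NULL,
                            eval = eval_config(),
                            density_bw = 0.05,
                            gwr_bandwidth = NULL,
                            seed = NULL) {
  if (!is.null(seed)) {
    world$seed <- as.integer(seed)
    eval$seed <- as.integer(seed)
  }
  if (is.null(scenarios))
    scenarios <- list(scenario_delta(2, 0.85, "SSP245-like"),
                      scenario_delta(4, 0.70, "SSP585-like"))
  structure(list(world = world, niche = niche, n_presences = n_presences,
                 min_area = min_area, target_length = target_length,
                 predictors = predictors, betas = betas,
                 class_sets = class_sets, scenarios = scenarios,
                 eval = eval, density_bw = density_bw,
                 gwr_bandwidth = gwr_bandwidth),
            class = "pipeline_config")
}

#' Default cold/wet-optimum niche for a synthetic world
#'
#' Optimum bio1 is placed at the 25th percentile of the network's bio1
#' distribution (a cool- but not coldest-edge optimum, mirroring a species
#' that occupies low-to-mid elevations with upslope refuge headroom) and
#' optimum bio12h at the 90th percentile (wet end). The temperature breadth
#' is one quarter of the 10-90 bio1 range (temperature is the decisive
#' axis); the precipitation breadth is the full 10-90 bio12h span with half
#' weight, since stream fishes track discharge gradients loosely and the
#' synthetic orographic precipitation range is spatially narrow. The
#' quantile anchors define the niche relative to the world's geometry; they
#' are part of the stated world, not tuning knobs.
#'
#' @param predictors per-reach predictor table with bio1 and bio12h.
#' @param baseline logit-scale baseline (default 2).
#' @return a \code{true_niche}.
#' @export
default_cold_wet_niche <- function(predictors, baseline = 2) {
  qb1 <- stats::quantile(predictors$bio1, c(0.1, 0.25, 0.9), names = FALSE)
  qph <- stats::quantile(predictors$bio12h, c(0.1, 0.9), names = FALSE)
  true_niche(data.frame(
    predictor = c("bio1", "bio12h"),
    optimum = c(qb1[2], qph[2]),
    breadth = c(max((qb1[3] - qb1[1]) / 4, 0.1),
                max(diff(qph), 1)),
    weight = c(2, 0.5)), baseline = baseline)
}

#' Run the full riverscape SDM pipeline
#'
#' Sequences the stages: synthetic world, stream network, climate
#' downscaling, bioclim/hydroclim predictors, presence sampling from the
#' true niche, candidate-model grid and selection, present and per-scenario
#' future suitability, three-class maps, change accounting and density
#' summaries. Deterministic given the config seed.
#'
#' @param config a \code{pipeline_config}.
#' @param outdir output directory; NULL skips writing artifacts.
#' @param quiet suppress stage log lines on stderr.
#' @return a run report list (see details in the package vignette).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_stage <- function(...) if (!quiet)
    message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, "secs")), ...)
  stage <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  wc <- config$world
  dem <- stage("synth: DEM", make_dem(wc))
  clim <- stage("synth: climate", make_monthly_climate(dem, wc))
  network <- stage("network", build_stream_network(
    dem, min_area = config$min_area, target_length = config$target_length))
  fine <- stage("downscale", downscale_climate(
    clim$coarse, clim$dem_coarse, dem,
    stations = clim$stations, bandwidth = config$gwr_bandwidth))
  catch <- catchment_sets(network)
  pred_present <- stage("bioclim", reach_predictors(network, fine, catch))
  niche <- config$niche
  if (is.null(niche)) niche <- default_cold_wet_niche(pred_present)
  suit_true <- true_suitability(pred_present, niche)
  occ <- stage("presences", sample_presences(
    network, suit_true, config$n_presences,
    seed = stage_seed(wc$seed, "presences")))
  occ_idx <- match(occ$reach_id, pred_present$reach_id)
  pres <- pred_present[occ_idx, config$predictors, drop = FALSE]
  bg <- pred_present[, config$predictors, drop = FALSE]
  cand <- stage("candidate grid", candidate_grid(
    pres, bg, config$betas, config$class_sets, config$eval))
  best <- select_best(cand, config$eval$omission_E)
  cand$selected <- seq_len(nrow(cand)) == as.integer(rownames(best)[1])
  fs <- build_features(bg, strsplit(best$classes, "\\+")[[1]])
  model <- stage("final fit", fit_maxent(pres, bg, fs, beta = best$beta))
  p_present <- predict(model, bg)
  p_train <- predict(model, pres)
  mtp <- mtp_threshold(p_train)
  mtp_eff <- min(max(mtp, 1e-6), 0.499)   # classifier demands mtp in (0,.5)
  cls_present <- classify_suitability(p_present, mtp_eff)
  lengths_m <- network$reaches$length_m
  elev <- network$reaches$elevation
  present_km <- suitable_length_km(cls_present, lengths_m)
  scenario_out <- list()
  for (sc in config$scenarios) {
    fut_clim <- apply_scenario(fine, sc)
    pred_fut <- reach_predictors(network, fut_clim, catch)
    p_future <- predict(model, pred_fut[, config$predictors, drop = FALSE])
    cls_future <- classify_suitability(p_future, mtp_eff)
    chg <- change_analysis(cls_present, cls_future, lengths_m)
    ed <- suppressWarnings(
      elevation_density(p_future, elev, mtp_eff))
    scenario_out[[sc$label]] <- list(
      delta = sc, p = p_future, classes = cls_future, change = chg,
      km = suitable_length_km(cls_future, lengths_m),
      mean_suitable_elevation = attr(ed, "mean_elevation"))
    log_stage(sprintf("scenario %s: stable %.1f%%, lost %.1f%%, new %.1f%%",
                      sc$label, chg$stable_pct, chg$lost_pct, chg$new_pct))
  }
  ed0 <- suppressWarnings(elevation_density(p_present, elev, mtp_eff))
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("streamsdm")),
      seed = wc$seed, config_hash = config_hash(config),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S")),
    n_reaches = nrow(network$reaches),
    n_presences = nrow(occ),
    selected_model = list(beta = best$beta, classes = best$classes,
                          aicc = best$aicc, auc = best$auc,
                          auc_ratio = best$auc_ratio,
                          omission = best$omission, k = best$k),
    mtp = mtp, mtp_effective = mtp_eff,
    present_km = as.list(present_km),
    mean_suitable_elevation_present = attr(ed0, "mean_elevation"),
    scenarios = lapply(scenario_out, function(s) list(
      label = s$delta$label, delta_t = s$delta$delta_t,
      precip_scale = s$delta$precip_scale,
      stable_km = s$change$stable_km, lost_km = s$change$lost_km,
      new_km = s$change$new_km,
      stable_pct = s$change$stable_pct, lost_pct = s$change$lost_pct,
      new_pct = s$change$new_pct,
      suitable_km = unname(s$km["suitable"]),
      mean_suitable_elevation = s$mean_suitable_elevation)))
  result <- list(report = report, network = network, model = model,
                 candidates = cand, predictors = pred_present,
                 niche = niche, occurrences = occ,
                 p_present = p_present, classes_present = cls_present,
                 scenarios = scenario_out, fine_climate = fine)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir, dem)
  log_stage("done")
  result
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  drop_fn <- rapply(unclass(config), function(x) x, how = "replace")
  jsonlite::write_json(drop_fn, tmp, auto_unbox = TRUE, digits = 10,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(result, outdir, dem) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_asc_grid(dem, file.path(outdir, "dem.asc"))
  write_network_geojson(result$network, result$classes_present,
                        file.path(outdir, "network.geojson"))
  tab <- result$predictors
  tab$p_present <- result$p_present
  tab$class_present <- as.character(result$classes_present)
  for (nm in names(result$scenarios)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    tab[[paste0("p_", safe)]] <- result$scenarios[[nm]]$p
    tab[[paste0("class_", safe)]] <-
      as.character(result$scenarios[[nm]]$classes)
  }
  utils::write.csv(tab, file.path(outdir, "reach_table.csv"),
                   row.names = FALSE)
  utils::write.csv(result$candidates, file.path(outdir, "candidates.csv"),
                   row.names = FALSE)
  utils::write.csv(result$occurrences, file.path(outdir, "occurrences.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outdir)
}

#' Write the reach network as GeoJSON
#'
#' One LineString feature per reach with its attributes (and habitat class
#' when supplied).
#'
#' @param network a \code{stream_network}.
#' @param classes optional habitat class factor per reach.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_geojson <- function(network, classes = NULL, path) {
  r <- network$reaches
  feats <- lapply(seq_len(nrow(r)), function(i) {
    props <- as.list(r[i, setdiff(names(r), c("up_x", "up_y", "down_x",
                                              "down_y"))])
    if (!is.null(classes)) props$habitat_class <- as.character(classes[i])
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = unname(
                           apply(network$geometry[[i]], 1, c,
                                 simplify = FALSE))),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8, force = TRUE)
  invisible(path)
}

#' Write / read a plain-text key:value config file
#'
#' Flat serialization of the world-configuration fields.
#'
#' @param config a \code{synth_world_config}.
#' @param path file path.
#' @return `path` (writer); \code{synth_world_config} (reader).
#' @export
write_world_config <- function(config, path) {
  flat <- unclass(config)
  writeLines(sprintf("%s: %s", names(flat),
                     vapply(flat, format, "", digits = 12)), path)
  invisible(path)
}

#' @rdname write_world_config
#' @export
read_world_config <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, ":\\s*")
  vals <- lapply(kv, function(p) as.numeric(p[2]))
  names(vals) <- vapply(kv, `[`, "", 1L)
  do.call(world_config, vals)
}
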