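## Candidate-model grid and evaluation in the style of the Kuenm workflow:
## random 70/30 occurrence partitions, omission rates, partial ROC with
## bootstrap AUC ratios, full AUC, and the significance -> omission -> AICc
## selection cascade.

#' Evaluation configuration
#'
#' @param train_fraction fraction of occurrences used for training (0.7).
#' @param replicates number of random partitions (10).
#' @param omission_E allowed omission percentage E (default 5).
#' @param proc_iterations bootstrap iterations for partial ROC (500).
#' @param proc_sample_fraction fraction of test presences resampled per
#'   bootstrap iteration (0.5).
#' @param seed integer seed.
#' @return an \code{eval_config} list.
#' @export
eval_config <- function(train_fraction = 0.7, replicates = 10L,
                        omission_E = 5, proc_iterations = 500L,
                        proc_sample_fraction = 0.5, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (omission_E <= 0 || omission_E >= 50)
    stop("omission_E must be in (0, 50)")
  structure(list(train_fraction = train_fraction,
                 replicates = as.integer(replicates),
                 omission_E = omission_E,
                 proc_iterations = as.integer(proc_iterations),
                 proc_sample_fraction = proc_sample_fraction,
                 seed = as.integer(seed)),
            class = "eval_config")
}

#' Random train/test partitions of occurrences
#'
#' Train size is \code{round(train_fraction * n)}; each replicate's train
#' and test are disjoint and exhaustive.
#'
#' @param occurrences data.frame (or vector of ids).
#' @param config an \code{eval_config}.
#' @return list of \code{replicates} lists with integer index vectors
#'   \code{train} and \code{test}.
#' @export
split_occurrences <- function(occurrences, config = eval_config()) {
  n <- if (is.data.frame(occurrences)) nrow(occurrences)
       else length(occurrences)
  if (n < 5L) stop("at least 5 occurrences are required")
  ntrain <- round(config$train_fraction * n)
  if (ntrain >= n || ntrain < 1L)
    stop("partition leaves an empty train or test set")
  set.seed(config$seed)
  lapply(seq_len(config$replicates), function(i) {
    tr <- sort(sample.int(n, ntrain))
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
}

#' Omission rate of test presences at a threshold
#'
#' @param test_suitability suitability of held-out presences.
#' @param threshold suitability threshold.
#' @return fraction of test presences with suitability <= threshold.
#' @export
omission_rate <- function(test_suitability, threshold) {
  if (length(test_suitability) < 1L) stop("no test suitabilities")
  mean(test_suitability <= threshold)
}

#' Full AUC (Mann-Whitney)
#'
#' Probability that a random presence outscores a random background point,
#' ties counted one half.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in [0, 1].
#' @export
full_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np < 1L || nb < 1L) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

## partial AUC ratio for one set of presence scores; the ROC here follows
## the niche-modelling convention: x = proportion of background predicted
## present (1 - specificity proxy), y = sensitivity, restricted to the band
## y >= 1 - E/100; ratio = area under the curve / area under y = x there
proc_ratio_once <- function(pres, bg_sorted, E) {
  ymin <- 1 - E / 100
  thr <- sort(unique(c(pres, bg_sorted)))
  nb <- length(bg_sorted)
  ## fraction >= t via binary search on the sorted background
  x <- 1 - (findInterval(thr, bg_sorted, left.open = TRUE)) / nb
  y <- 1 - (findInterval(thr, sort(pres), left.open = TRUE)) / length(pres)
  ## descending threshold order makes (x, y) increase from (0,0) to (1,1)
  o <- order(thr, decreasing = TRUE)
  x <- c(0, x[o], 1); y <- c(0, y[o], 1)
  keep <- y >= ymin
  if (!any(keep)) return(NA_real_)
  i0 <- which(keep)[1]
  if (i0 > 1L && y[i0] > ymin && y[i0 - 1] < y[i0]) {
    ## interpolate the crossing of y = ymin on the segment entering the band
    f <- (ymin - y[i0 - 1]) / (y[i0] - y[i0 - 1])
    x0 <- x[i0 - 1] + f * (x[i0] - x[i0 - 1])
    xs <- c(x0, x[keep]); ys <- c(ymin, y[keep])
  } else { xs <- x[keep]; ys <- y[keep] }
  pa_model <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  pa_rand <- (xs[length(xs)]^2 - xs[1]^2) / 2
  if (pa_rand <= 0) return(NA_real_)
  pa_model / pa_rand
}

#' Partial ROC evaluation
#'
#' ROC analysis restricted to the low-omission region (sensitivity >=
#' 1 - E/100). Per bootstrap iteration, \code{sample_fraction} of the test
#' presences are resampled with replacement and the partial AUC over the
#' band is divided by its random expectation (the area under y = x over the
#' same band); a ratio of 1 is random performance. The p-value is the
#' fraction of iterations with ratio <= 1.
#'
#' @param test_suitability held-out presence suitabilities (>= 5).
#' @param background_suitability background suitabilities.
#' @param E omission percentage defining the band (default 5).
#' @param iterations bootstrap iterations (default 500).
#' @param sample_fraction presence resampling fraction (default 0.5).
#' @param seed integer seed.
#' @return list(auc_ratio = mean bootstrap AUC ratio, p_value, ratios).
#' @export
partial_roc <- function(test_suitability, background_suitability, E = 5,
                        iterations = 500L, sample_fraction = 0.5, seed = 1L) {
  if (length(test_suitability) < 5L)
    stop("at least 5 test presences are required")
  if (stats::sd(c(test_suitability, background_suitability)) == 0)
    return(list(auc_ratio = 1, p_value = 1,
                ratios = rep(1, iterations)))
  set.seed(as.integer(seed))
  bgs <- sort(background_suitability)
  np <- length(test_suitability)
  m <- max(1L, round(sample_fraction * np))
  ratios <- vapply(seq_len(iterations), function(i) {
    proc_ratio_once(test_suitability[sample.int(np, m, replace = TRUE)],
                    bgs, E)
  }, numeric(1))
  ok <- !is.na(ratios)
  if (!any(ok)) return(list(auc_ratio = NA_real_, p_value = NA_real_,
                            ratios = ratios))
  list(auc_ratio = mean(ratios[ok]),
       p_value = mean(ratios[ok] <= 1),
       ratios = ratios)
}

#' Fit and evaluate a Kuenm-style candidate grid
#'
#' Cartesian product of regularization multipliers and feature-class sets
#' (duplicates removed). Each candidate is fitted on the training
#' partition; omission rate at E (threshold = E-percentile of training
#' presence suitability) and partial ROC are computed on the test partition
#' against the background; AICc is computed on a refit to all occurrences
#' (Kuenm convention). Individual fit failures are recorded and the grid
#' continues.
#'
#' @param presences,background data.frames of predictor rows.
#' @param betas numeric vector of regularization multipliers.
#' @param class_sets list (or character vector) of feature-class sets, e.g.
#'   \code{list("l", "lq", "lqh")}.
#' @param config an \code{eval_config}.
#' @return data.frame, one row per candidate, with metrics and notes.
#' @export
candidate_grid <- function(presences, background, betas, class_sets,
                           config = eval_config()) {
  if (length(betas) < 1L || length(class_sets) < 1L)
    stop("betas and class_sets must be non-empty")
  if (is.character(class_sets)) class_sets <- as.list(class_sets)
  cls_id <- vapply(class_sets, function(cl)
    paste(sort(norm_classes(cl)), collapse = "+"), "")
  grid <- expand.grid(beta = betas, cls = seq_along(class_sets))
  grid$cls_id <- cls_id[grid$cls]
  grid <- grid[!duplicated(grid[, c("beta", "cls_id")]), ]
  part <- split_occurrences(presences, config)[[1L]]
  train <- presences[part$train, , drop = FALSE]
  test <- presences[part$test, , drop = FALSE]
  E <- config$omission_E
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    beta <- grid$beta[i]
    classes <- class_sets[[grid$cls[i]]]
    base <- data.frame(beta = beta, classes = grid$cls_id[i],
                       auc_ratio = NA_real_, proc_p = NA_real_,
                       omission = NA_real_, auc = NA_real_, aicc = NA_real_,
                       k = NA_integer_, valid = FALSE, note = "")
    tryCatch({
      fs <- build_features(background, classes)
      fit <- fit_maxent(train, background, fs, beta = beta)
      p_train <- predict(fit, train)
      p_test <- predict(fit, test)
      p_bg <- predict(fit, background)
      thr <- stats::quantile(p_train, E / 100, names = FALSE)
      pr <- partial_roc(p_test, p_bg, E = E,
                        iterations = config$proc_iterations,
                        sample_fraction = config$proc_sample_fraction,
                        seed = config$seed + i)
      full_fit <- fit_maxent(presences, background, fs, beta = beta)
      ic <- maxent_aicc(full_fit, presences, background)
      base$auc_ratio <- pr$auc_ratio; base$proc_p <- pr$p_value
      base$omission <- omission_rate(p_test, thr)
      base$auc <- full_auc(p_test, p_bg)
      base$aicc <- ic$aicc; base$k <- ic$k
      base$valid <- ic$valid
      if (!ic$valid) base$note <- "AICc undefined (n <= k + 1)"
      base
    }, error = function(e) { base$note <- conditionMessage(e); base })
  })
  out <- do.call(rbind, rows)
  out$delta_aicc <- out$aicc - min(out$aicc, na.rm = TRUE)
  out$selected <- FALSE
  out
}

#' Select the best candidate model
#'
#' Filter cascade: statistical significance (partial-ROC p < 0.05), then
#' omission rate <= E/100, then minimum AICc among the survivors. If a
#' filter empties the set, selection falls back to the previous set with a
#' warning. Ties break to the smaller beta, then to fewer feature classes.
#'
#' @param candidates data.frame from \code{\link{candidate_grid}}.
#' @param E omission percentage (default 5).
#' @return the selected candidate row (with \code{selected = TRUE}).
#' @export
select_best <- function(candidates, E = 5) {
  if (nrow(candidates) < 1L) stop("empty candidate table")
  pool <- candidates[!is.na(candidates$aicc), , drop = FALSE]
  if (nrow(pool) == 0L) {
    warning("no candidate has a defined AICc; selecting on the full table")
    pool <- candidates
  }
  sig <- pool[!is.na(pool$proc_p) & pool$proc_p < 0.05, , drop = FALSE]
  if (nrow(sig) == 0L) {
    warning("no statistically significant candidate; relaxing the filter")
    sig <- pool
  }
  om <- sig[!is.na(sig$omission) & sig$omission <= E / 100, , drop = FALSE]
  if (nrow(om) == 0L) {
    warning("no candidate meets the omission criterion; relaxing the filter")
    om <- sig
  }
  nclasses <- nchar(gsub("[^+]", "", om$classes)) + 1L
  o <- order(om$aicc, om$beta, nclasses)
  best <- om[o[1L], , drop = FALSE]
  best$selected <- TRUE
  best
}
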