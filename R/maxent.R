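## From-scratch maximum-entropy presence-background model: feature
## construction (linear, quadratic, product, hinge, threshold), L1-penalized
## fitting of the Gibbs distribution by monotone proximal gradient descent,
## raw / logistic / cloglog output transforms, and the MaxEnt-specific AICc.

FEATURE_CLASSES <- c("linear", "quadratic", "product", "hinge", "threshold")

norm_classes <- function(classes) {
  map <- c(l = "linear", q = "quadratic", p = "product", h = "hinge",
           t = "threshold")
  cl <- unique(unlist(strsplit(tolower(classes), "")))
  if (all(classes %in% FEATURE_CLASSES)) return(unique(classes))
  if (!all(cl %in% names(map)))
    stop("unknown feature class letters: ",
         paste(setdiff(cl, names(map)), collapse = ""))
  unname(map[cl])
}

#' Build a MaxEnt feature set from a background sample
#'
#' Expands the requested feature classes over the predictors: linear (x),
#' quadratic (x^2), product (x_i x_j), forward and reverse hinge ramps with
#' knots at equally spaced background quantiles, and threshold indicators at
#' the same knots. Every feature is min-max scaled to [0, 1] over the
#' background; constant predictors are dropped with a warning.
#'
#' @param background data.frame of background predictor values.
#' @param classes feature classes, full names or letters ("lqph" style).
#' @param knots_per_hinge number of interior knots for hinge/threshold
#'   features (default 5).
#' @return a \code{feature_set}.
#' @export
build_features <- function(background, classes = c("linear", "quadratic"),
                           knots_per_hinge = 5L) {
  classes <- norm_classes(classes)
  background <- as.data.frame(background)
  if (nrow(background) < 2L) stop("at least 2 background points required")
  keep <- vapply(background, function(x) is.numeric(x) && !anyNA(x) &&
                   stats::sd(x) > 0, logical(1))
  if (any(!keep))
    warning("constant, NA-containing or non-numeric predictor(s) dropped: ",
            paste(names(background)[!keep], collapse = ", "))
  background <- background[, keep, drop = FALSE]
  if (ncol(background) < 1L)   # no information: empty set -> uniform model
    return(structure(list(defs = list(), vars = character(0),
                          ranges = list(), scale_min = numeric(0),
                          scale_max = numeric(0)), class = "feature_set"))
  vars <- names(background)
  defs <- list()
  add <- function(type, name, ...)
    defs[[length(defs) + 1L]] <<- c(list(type = type, name = name),
                                    list(...))
  for (v in vars) {
    if ("linear" %in% classes) add("linear", v, var = v)
    if ("quadratic" %in% classes) add("quadratic", paste0(v, "^2"), var = v)
  }
  if ("product" %in% classes && length(vars) > 1L)
    for (i in seq_len(length(vars) - 1L)) for (j in (i + 1L):length(vars))
      add("product", paste0(vars[i], "*", vars[j]),
          var = vars[i], var2 = vars[j])
  if (any(c("hinge", "threshold") %in% classes)) {
    probs <- seq(0, 1, length.out = knots_per_hinge + 2L)
    probs <- probs[-c(1L, length(probs))]
    for (v in vars) {
      x <- background[[v]]
      lo <- min(x); hi <- max(x)
      knots <- unique(stats::quantile(x, probs, names = FALSE))
      for (k in knots) {
        if ("hinge" %in% classes) {
          if (k < hi) add("hinge", sprintf("h(%s>%.6g)", v, k),
                          var = v, knot = k, lo = lo, hi = hi)
          if (k > lo) add("hinge_rev", sprintf("h(%s<%.6g)", v, k),
                          var = v, knot = k, lo = lo, hi = hi)
        }
        if ("threshold" %in% classes && k > lo && k < hi)
          add("threshold", sprintf("t(%s>%.6g)", v, k), var = v, knot = k)
      }
    }
  }
  fs <- structure(list(defs = defs, vars = vars,
                       ranges = lapply(background, range),
                       scale_min = NULL, scale_max = NULL),
                  class = "feature_set")
  raw <- feature_raw(fs, background)
  fs$scale_min <- apply(raw, 2, min)
  fs$scale_max <- apply(raw, 2, max)
  flat <- fs$scale_max - fs$scale_min <= 0
  if (any(flat)) {        # features constant on background carry no signal
    fs$defs <- fs$defs[!flat]
    fs$scale_min <- fs$scale_min[!flat]
    fs$scale_max <- fs$scale_max[!flat]
  }
  fs
}

#' @export
print.feature_set <- function(x, ...) {
  types <- vapply(x$defs, `[[`, "", "type")
  cat(sprintf("<feature_set> %d features over %d predictors (%s)\n",
              length(x$defs), length(x$vars),
              paste(names(table(types)), table(types), sep = ":",
                    collapse = ", ")))
  invisible(x)
}

feature_raw <- function(fs, data) {
  data <- as.data.frame(data)
  n <- nrow(data)
  out <- matrix(NA_real_, n, length(fs$defs))
  for (j in seq_along(fs$defs)) {
    d <- fs$defs[[j]]
    x <- data[[d$var]]
    out[, j] <- switch(d$type,
      linear = x,
      quadratic = x^2,
      product = x * data[[d$var2]],
      hinge = pmax(0, (x - d$knot) / (d$hi - d$knot)),
      hinge_rev = pmax(0, (d$knot - x) / (d$knot - d$lo)),
      threshold = as.numeric(x > d$knot))
  }
  colnames(out) <- vapply(fs$defs, `[[`, "", "name")
  out
}

#' Evaluate a feature set on predictor rows
#'
#' @param fs a \code{feature_set}.
#' @param data data.frame of predictors.
#' @param clamp clamp scaled features into [0, 1] (with a warning) when the
#'   data fall outside the training background range.
#' @return numeric matrix, one scaled feature per column.
#' @export
feature_matrix <- function(fs, data, clamp = TRUE) {
  raw <- feature_raw(fs, data)
  sc <- sweep(sweep(raw, 2, fs$scale_min), 2,
              fs$scale_max - fs$scale_min, "/")
  if (clamp && (any(sc < 0) || any(sc > 1))) {
    warning("feature values outside training scaling clamped to [0, 1]")
    sc <- pmin(pmax(sc, 0), 1)
  }
  sc
}

## class-specific default regularization scale, interpolated by presence
## sample size (log-linear between 1.0 at n = 10 and 0.05 at n = 100 for
## linear/quadratic/product, clamped; hinge 0.5; threshold 1.0)
class_reg_scale <- function(types, n_pres) {
  lq <- if (n_pres <= 10) 1.0 else if (n_pres >= 100) 0.05 else
    exp(log(1.0) + (log(0.05) - log(1.0)) *
          (log(n_pres) - log(10)) / (log(100) - log(10)))
  sc <- c(linear = lq, quadratic = lq, product = lq, hinge = 0.5,
          hinge_rev = 0.5, threshold = 1.0)
  unname(sc[types])
}

#' Fit a maximum-entropy presence-background model
#'
#' Maximizes the L1-penalized Gibbs log-likelihood
#' \deqn{\sum_{presences} \log(e^{\lambda f(x)} / Z) - \sum_j \beta_j
#'   |\lambda_j|,\quad Z = \sum_{background} e^{\lambda f}}
#' with \eqn{\beta_j = \beta c_j s_j / \sqrt{n}} where \eqn{s_j} is the
#' background standard deviation of feature j, n the presence count and
#' \eqn{c_j} a class-specific scale (linear/quadratic/product interpolated
#' log-linearly from 1.0 at n = 10 to 0.05 at n = 100; hinge 0.5; threshold
#' 1.0). The problem is convex; cyclic coordinate descent (per-feature
#' Newton step, soft threshold, halving line search — monotone by
#' construction) iterates until the relative objective change per sweep
#' falls below \code{tol} or \code{max_iter} sweeps are exhausted.
#'
#' @param presences,background data.frames of predictor rows.
#' @param feature_set a \code{feature_set} built on the background; built
#'   automatically (linear + quadratic) when NULL.
#' @param beta regularization multiplier (>= 0, default 1).
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence raises an error carrying
#'   the last relative gap.
#' @return a \code{maxent_model} with weights \code{lambda}, normalizer
#'   \code{Z}, entropy \code{H}, the per-iteration objective trace, and the
#'   feature set.
#' @export
fit_maxent <- function(presences, background, feature_set = NULL, beta = 1,
                       tol = 1e-8, max_iter = 500L) {
  if (beta < 0) stop("beta must be non-negative")
  if (nrow(presences) < 2L) stop("at least 2 presences required")
  if (is.null(feature_set))
    feature_set <- build_features(background, c("linear", "quadratic"))
  Fp <- feature_matrix(feature_set, presences, clamp = FALSE)
  Fb <- feature_matrix(feature_set, background, clamp = FALSE)
  np <- nrow(Fp); nb <- nrow(Fb); k <- ncol(Fb)
  if (k == 0L)     # no informative feature: the uniform Gibbs distribution
    return(structure(list(lambda = numeric(0), Z = nb, H = log(nb),
                          beta = beta, beta_j = numeric(0),
                          feature_set = feature_set, n_presences = np,
                          n_background = nb, objective_trace = np * log(nb),
                          transform = "cloglog"), class = "maxent_model"))
  s <- apply(Fb, 2, stats::sd)
  types <- vapply(feature_set$defs, `[[`, "", "type")
  bj <- beta * class_reg_scale(types, np) * s / sqrt(np)
  fbar <- colMeans(Fp)
  pen <- function(lam) sum(bj * abs(lam))
  logZ_of <- function(eta) { M <- max(eta); M + log(sum(exp(eta - M))) }
  smooth_of <- function(lam, eta) -np * sum(fbar * lam) + np * logZ_of(eta)
  ## one cyclic coordinate-descent sweep: exact 1-D Newton step + soft
  ## threshold per feature with a halving line search; monotone
  cd_sweep <- function(lam, eta, obj) {
    for (j in seq_len(k)) {
      M <- max(eta)
      w <- exp(eta - M)
      q <- w / sum(w)
      mu <- sum(q * Fb[, j])
      g <- np * (mu - fbar[j])
      h <- np * max(sum(q * Fb[, j]^2) - mu^2, 1e-10)
      z <- lam[j] * h - g
      dlt <- sign(z) * max(abs(z) - bj[j], 0) / h - lam[j]
      if (dlt == 0) next
      repeat {
        eta_c <- eta + dlt * Fb[, j]
        lam_c <- `[<-`(lam, j, lam[j] + dlt)
        cand_obj <- smooth_of(lam_c, eta_c) + pen(lam_c)
        if (cand_obj <= obj) { lam <- lam_c; eta <- eta_c; obj <- cand_obj
          break }
        dlt <- dlt / 2
        if (abs(dlt) < 1e-14) break
      }
    }
    list(lam = lam, eta = eta, obj = obj)
  }
  ## bound-constrained refinement of the equivalent smooth split problem
  ## (lambda = u - v, u, v >= 0), used when coordinate descent crawls along
  ## a valley of strongly correlated (hinge) features
  refine_lbfgsb <- function(lam, obj) {
    f_uv <- function(uv) {
      l <- uv[seq_len(k)] - uv[k + seq_len(k)]
      smooth_of(l, drop(Fb %*% l)) + sum(bj * (uv[seq_len(k)] +
                                                 uv[k + seq_len(k)]))
    }
    g_uv <- function(uv) {
      l <- uv[seq_len(k)] - uv[k + seq_len(k)]
      eta <- drop(Fb %*% l)
      M <- max(eta); w <- exp(eta - M); q <- w / sum(w)
      gsm <- np * (drop(crossprod(Fb, q)) - fbar)
      c(gsm + bj, -gsm + bj)
    }
    uv <- c(pmax(lam, 0), pmax(-lam, 0))
    prev <- Inf
    for (r in 1:6) {
      o <- stats::optim(uv, f_uv, g_uv, method = "L-BFGS-B", lower = 0,
                        control = list(maxit = 500L, factr = 10))
      uv <- o$par
      if (o$convergence == 0 ||
            prev - o$value < 1e-11 * max(1, abs(prev))) break
      prev <- o$value
    }
    l <- uv[seq_len(k)] - uv[k + seq_len(k)]
    if (o$value < obj) list(lam = l, eta = drop(Fb %*% l), obj = o$value)
    else NULL
  }
  lam <- numeric(k)
  eta <- numeric(nb)
  obj <- smooth_of(lam, eta) + pen(lam)
  trace <- obj
  lam_prev <- lam
  converged <- FALSE; gap <- NA_real_; last_refine <- -20L
  for (it in seq_len(max_iter)) {
    obj_start <- obj
    st <- cd_sweep(lam, eta, obj)
    lam <- st$lam; eta <- st$eta; obj <- st$obj
    ## extrapolation along the sweep direction counters zigzagging
    dirv <- lam - lam_prev
    lam_prev <- lam
    if (any(dirv != 0)) for (tmul in c(16, 4, 1)) {
      cand <- lam + tmul * dirv
      eta_c <- drop(Fb %*% cand)
      cobj <- smooth_of(cand, eta_c) + pen(cand)
      if (cobj < obj) { lam <- cand; eta <- eta_c; obj <- cobj; break }
    }
    gap <- (obj_start - obj) / max(1, abs(obj_start))
    if (gap > 0 && gap < 1e4 * tol && it - last_refine >= 20L) {
      ## crawling: hand over to the smooth bound-constrained solver, then
      ## certify with further coordinate sweeps
      ref <- refine_lbfgsb(lam, obj)
      last_refine <- it
      if (!is.null(ref)) { lam <- ref$lam; eta <- ref$eta; obj <- ref$obj
        lam_prev <- lam }
      gap <- (obj_start - obj) / max(1, abs(obj_start))
    }
    trace <- c(trace, obj)
    if (gap < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf(
      "maxent solver did not converge in %d iterations (last gap %.3g)",
      max_iter, gap))
  eta <- drop(Fb %*% lam)
  M <- max(eta)
  Z <- sum(exp(eta - M)) * exp(M)
  raw <- exp(eta) / Z
  H <- -sum(raw * log(raw))
  structure(list(lambda = stats::setNames(lam, colnames(Fb)), Z = Z, H = H,
                 beta = beta, beta_j = bj, feature_set = feature_set,
                 n_presences = np, n_background = nb,
                 objective_trace = trace, transform = "cloglog"),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> %d features (%d active), beta %.3g, ",
                     "n_pres %d, n_bg %d, H %.4g\n"),
              length(x$lambda), sum(x$lambda != 0), x$beta, x$n_presences,
              x$n_background, x$H))
  invisible(x)
}

#' Predict suitability from a fitted MaxEnt model
#'
#' Raw output \eqn{r(x) = e^{\lambda f(x)}/Z} (sums to 1 over the training
#' background); logistic \eqn{r e^H / (1 + r e^H)}; cloglog
#' \eqn{1 - \exp(-r e^H)} (the MaxEnt 3.4.4 default suitability scale P).
#'
#' @param object a \code{maxent_model}.
#' @param newdata data.frame of predictor rows.
#' @param transform "cloglog" (default), "logistic" or "raw".
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.maxent_model <- function(object, newdata,
                                 transform = c("cloglog", "logistic", "raw"),
                                 ...) {
  transform <- match.arg(transform)
  if (length(object$lambda) == 0L) {
    eta <- rep(0, nrow(as.data.frame(newdata)))
  } else {
    Fm <- feature_matrix(object$feature_set, newdata, clamp = TRUE)
    eta <- drop(Fm %*% object$lambda)
  }
  r <- exp(eta) / object$Z
  switch(transform,
         raw = r,
         logistic = r * exp(object$H) / (1 + r * exp(object$H)),
         cloglog = 1 - exp(-r * exp(object$H)))
}

#' MaxEnt-style AICc
#'
#' log-likelihood is the sum over presences of the log raw output normalized
#' over the supplied background; k counts the non-zero feature weights.
#' Undefined (flagged invalid) when n_presences <= k + 1.
#'
#' @param model a \code{maxent_model}.
#' @param presences,background data.frames of predictor rows.
#' @return list(aicc, k, loglik, valid).
#' @export
maxent_aicc <- function(model, presences, background) {
  if (length(model$lambda) == 0L) {
    eta_b <- rep(0, nrow(background)); eta_p <- rep(0, nrow(presences))
  } else {
    eta_b <- drop(feature_matrix(model$feature_set, background,
                                 clamp = TRUE) %*% model$lambda)
    eta_p <- drop(feature_matrix(model$feature_set, presences,
                                 clamp = TRUE) %*% model$lambda)
  }
  M <- max(eta_b)
  logZ <- M + log(sum(exp(eta_b - M)))
  ll <- sum(eta_p - logZ)
  k <- sum(model$lambda != 0)
  n <- nrow(presences)
  if (n <= k + 1L)
    return(list(aicc = NA_real_, k = k, loglik = ll, valid = FALSE))
  list(aicc = 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1), k = k,
       loglik = ll, valid = TRUE)
}

#' Serialize a MaxEnt model as a plain-text lambdas file + JSON header
#'
#' @param model a \code{maxent_model}.
#' @param path base path; writes `<path>.lambdas.csv` and `<path>.json`.
#' @return invisibly, the two file paths.
#' @export
write_maxent_model <- function(model, path) {
  fs <- model$feature_set
  lam <- data.frame(feature = names(model$lambda),
                    type = vapply(fs$defs, `[[`, "", "type"),
                    lambda = unname(model$lambda),
                    scale_min = unname(fs$scale_min),
                    scale_max = unname(fs$scale_max))
  f1 <- paste0(path, ".lambdas.csv")
  utils::write.csv(lam, f1, row.names = FALSE)
  hdr <- list(beta = model$beta, Z = model$Z, H = model$H,
              transform = model$transform, n_presences = model$n_presences,
              n_background = model$n_background)
  f2 <- paste0(path, ".json")
  jsonlite::write_json(hdr, f2, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2))
}
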