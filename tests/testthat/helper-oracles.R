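## Independent oracles used across the suite. These deliberately use naive
## enumeration / brute force and never share code with the package
## implementation they check.

## brute-force pit scan: interior cells strictly lower than all 8 neighbours
oracle_find_pits <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  pits <- integer(0)
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    nb <- c(z[r - 1, c - 1], z[r - 1, c], z[r - 1, c + 1],
            z[r, c - 1], z[r, c + 1],
            z[r + 1, c - 1], z[r + 1, c], z[r + 1, c + 1])
    if (all(z[r, c] < nb)) pits <- c(pits, (c - 1) * nr + r)
  }
  pits
}

## exhaustive steepest-descent direction for one cell (same precedence
## convention, re-derived independently from first principles)
oracle_d8_cell <- function(z, r, c, cell) {
  dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  best <- 0; bestk <- NA_integer_
  for (k in 1:8) {
    rr <- r + dr[k]; cc <- c + dc[k]
    if (rr < 1 || rr > nrow(z) || cc < 1 || cc > ncol(z)) next
    drop <- (z[r, c] - z[rr, cc]) / (sqrt(dr[k]^2 + dc[k]^2) * cell)
    if (drop > best) { best <- drop; bestk <- k }
  }
  bestk   # NA when no lower neighbour
}

## reachability oracle for accumulation: for every cell, walk every other
## cell's flow path and count how many pass through it
oracle_accumulation <- function(dirmat, cell) {
  dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  nr <- nrow(dirmat); nc <- ncol(dirmat)
  acc <- matrix(0, nr, nc)
  for (r0 in 1:nr) for (c0 in 1:nc) {
    r <- r0; c <- c0
    repeat {
      acc[r, c] <- acc[r, c] + 1
      d <- dirmat[r, c]
      if (is.na(d) || d == 0) break
      r2 <- r + dr[d]; c2 <- c + dc[d]
      r <- r2; c <- c2
    }
  }
  acc
}

## window-enumeration bioclim oracle: plain loops over the 12 wrap-around
## quarters, one site at a time
oracle_bioclim19 <- function(tmin, tmax, prcp) {
  tmean <- (tmin + tmax) / 2
  qidx <- lapply(1:12, function(m) ((m - 1 + 0:2) %% 12) + 1)
  qt <- sapply(qidx, function(i) mean(tmean[i]))
  qp <- sapply(qidx, function(i) sum(prcp[i]))
  wet <- which.max(qp); dry <- which.min(qp)
  warm <- which.max(qt); cold <- which.min(qt)
  popsd <- function(x) sqrt(mean((x - mean(x))^2))
  b2 <- mean(tmax - tmin); b5 <- max(tmax); b6 <- min(tmin); b7 <- b5 - b6
  b12 <- sum(prcp)
  c(bio1 = mean(tmean), bio2 = b2,
    bio3 = if (b7 == 0) 0 else b2 / b7 * 100,
    bio4 = popsd(tmean) * 100, bio5 = b5, bio6 = b6, bio7 = b7,
    bio8 = qt[wet], bio9 = qt[dry], bio10 = qt[warm], bio11 = qt[cold],
    bio12 = b12, bio13 = max(prcp), bio14 = min(prcp),
    bio15 = 100 * popsd(prcp) / (1 + b12 / 12),
    bio16 = qp[wet], bio17 = qp[dry], bio18 = qp[warm], bio19 = qp[cold])
}

## generic convex-optimizer oracle for the penalized maxent objective:
## split lambda = u - v with box constraints, solved by stats::optim
## L-BFGS-B with numerical-gradient-free analytic gradient, cold start,
## high precision
oracle_maxent_lambda <- function(Fp, Fb, bj) {
  np <- nrow(Fp); k <- ncol(Fb)
  fbar <- colMeans(Fp)
  obj <- function(uv) {
    lam <- uv[1:k] - uv[(k + 1):(2 * k)]
    eta <- drop(Fb %*% lam)
    M <- max(eta)
    -np * sum(fbar * lam) + np * (M + log(sum(exp(eta - M)))) +
      sum(bj * (uv[1:k] + uv[(k + 1):(2 * k)]))
  }
  grad <- function(uv) {
    lam <- uv[1:k] - uv[(k + 1):(2 * k)]
    eta <- drop(Fb %*% lam)
    M <- max(eta); w <- exp(eta - M); q <- w / sum(w)
    gsm <- np * (drop(crossprod(Fb, q)) - fbar)
    c(gsm + bj, -gsm + bj)
  }
  uv <- rep(0, 2 * k)
  for (r in 1:10) {
    o <- stats::optim(uv, obj, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    ## BFGS ignores bounds; project and polish with L-BFGS-B
    o <- stats::optim(pmax(o$par, 0), obj, grad, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 2000, factr = 1))
    if (isTRUE(all.equal(uv, o$par, tolerance = 1e-12))) break
    uv <- o$par
  }
  o$par[1:k] - o$par[(k + 1):(2 * k)]
}

## hand kriging system solve for a small sample set and one target
oracle_krige_point <- function(sx, sy, sv, gammafun, tx, ty) {
  n <- length(sv)
  G <- matrix(0, n + 1, n + 1)
  for (i in 1:n) for (j in 1:n)
    G[i, j] <- gammafun(sqrt((sx[i] - sx[j])^2 + (sy[i] - sy[j])^2))
  G[n + 1, 1:n] <- 1; G[1:n, n + 1] <- 1
  g0 <- c(vapply(1:n, function(i)
    gammafun(sqrt((sx[i] - tx)^2 + (sy[i] - ty)^2)), numeric(1)), 1)
  w <- solve(G, g0)
  list(pred = sum(w[1:n] * sv), weights = w[1:n])
}

## tiny deterministic test world shared by several files
tiny_world <- function(seed = 7, rows = 32L, cols = 32L) {
  world_config(grid_rows = rows, grid_cols = cols, seed = seed,
               station_count = 10L, coarse_factor = 4L)
}
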