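## D8 hydrological characterization: sink filling (priority flood), steepest
## descent routing with deterministic flat resolution, accumulation, stream
## extraction, 100 m reach segmentation, and the geophysical reach attributes.

## simple binary min-heap keyed by (elevation, insertion order); stable pops
heap_new <- function(capacity) {
  env <- new.env(parent = emptyenv())
  env$key <- numeric(capacity); env$ord <- numeric(capacity)
  env$val <- integer(capacity); env$n <- 0L; env$count <- 0
  env
}
heap_less <- function(h, i, j) {
  h$key[i] < h$key[j] || (h$key[i] == h$key[j] && h$ord[i] < h$ord[j])
}
heap_push <- function(h, key, val) {
  h$n <- h$n + 1L; h$count <- h$count + 1
  if (h$n > length(h$key)) {   # grow
    h$key <- c(h$key, numeric(h$n)); h$ord <- c(h$ord, numeric(h$n))
    h$val <- c(h$val, integer(h$n))
  }
  i <- h$n; h$key[i] <- key; h$ord[i] <- h$count; h$val[i] <- val
  while (i > 1L) {
    p <- i %/% 2L
    if (heap_less(h, i, p)) {
      h$key[c(i, p)] <- h$key[c(p, i)]; h$ord[c(i, p)] <- h$ord[c(p, i)]
      h$val[c(i, p)] <- h$val[c(p, i)]; i <- p
    } else break
  }
}
heap_pop <- function(h) {
  out <- h$val[1L]
  h$key[1L] <- h$key[h$n]; h$ord[1L] <- h$ord[h$n]; h$val[1L] <- h$val[h$n]
  h$n <- h$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L; s <- i
    if (l <= h$n && heap_less(h, l, s)) s <- l
    if (r <= h$n && heap_less(h, r, s)) s <- r
    if (s == i) break
    h$key[c(i, s)] <- h$key[c(s, i)]; h$ord[c(i, s)] <- h$ord[c(s, i)]
    h$val[c(i, s)] <- h$val[c(s, i)]; i <- s
  }
  out
}

## neighbour indices of cell idx in D8 precedence order; NA where off-grid
d8_neighbours <- function(nr, nc, idx) {
  r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
  rr <- r + D8_DR; cc <- c + D8_DC
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  out <- rep(NA_integer_, 8L)
  out[ok] <- (cc[ok] - 1L) * nr + rr[ok]
  out
}

#' Fill depressions in a DEM (priority flood)
#'
#' Raises every interior depression to its lowest pour point so that every
#' cell has a monotone non-increasing 8-neighbour path to the boundary.
#' Output >= input everywhere; cells not in a depression are untouched.
#' NA (nodata) cells act as additional drainage boundaries.
#'
#' @param dem an elevation \code{river_grid}.
#' @return the filled \code{river_grid}.
#' @export
fill_sinks <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (all(is.na(z))) stop("DEM is entirely nodata")
  filled <- z
  visited <- is.na(z)           # nodata never processed
  h <- heap_new(2L * (nr + nc))
  ## seed: boundary cells and cells adjacent to nodata
  edge <- unique(c(which(row(z) == 1L | row(z) == nr |
                           col(z) == 1L | col(z) == nc)))
  if (any(is.na(z))) {
    nas <- which(is.na(z))
    adj <- unlist(lapply(nas, function(i) d8_neighbours(nr, nc, i)))
    edge <- unique(c(edge, adj[!is.na(adj)]))
  }
  edge <- edge[!is.na(z[edge])]
  for (i in edge) { visited[i] <- TRUE; heap_push(h, filled[i], i) }
  while (h$n > 0L) {
    c0 <- heap_pop(h)
    for (nb in d8_neighbours(nr, nc, c0)) {
      if (is.na(nb) || visited[nb]) next
      visited[nb] <- TRUE
      filled[nb] <- max(filled[nb], filled[c0])
      heap_push(h, filled[nb], nb)
    }
  }
  river_grid(filled, dem$cell_size, dem$origin)
}

#' D8 flow directions
#'
#' Each cell points to its steepest-descent neighbour (drop divided by
#' centre-to-centre distance, diagonals sqrt(2) x cell). Codes 1..8 follow
#' the fixed precedence E, SE, S, SW, W, NW, N, NE, which also breaks ties;
#' 0 marks an outlet (no lower neighbour on the boundary or next to nodata).
#' Cells in flats are resolved iteratively toward the nearest already-routed
#' equal-elevation neighbour, guaranteeing an acyclic field.
#'
#' @param filled_dem sink-filled \code{river_grid}.
#' @return a \code{flow_grid}: list(direction matrix, cell_size, origin).
#' @export
flow_direction <- function(filled_dem) {
  z <- filled_dem$values
  nr <- nrow(z); nc <- ncol(z)
  dir <- matrix(NA_integer_, nr, nc)
  cells <- which(!is.na(z))
  is_boundary <- function(i) {
    nbs <- d8_neighbours(nr, nc, i)
    any(is.na(nbs)) || any(is.na(z[nbs[!is.na(nbs)]]))
  }
  unresolved <- integer(0)
  for (i in cells) {
    nbs <- d8_neighbours(nr, nc, i)
    drop <- (z[i] - z[nbs]) / (D8_DIST * filled_dem$cell_size)
    drop[is.na(nbs)] <- NA
    drop[!is.na(nbs) & is.na(z[nbs])] <- NA
    if (any(drop > 0, na.rm = TRUE)) {
      dir[i] <- which.max(drop)       # first max = precedence tie-break
    } else if (is_boundary(i)) {
      dir[i] <- 0L
    } else {
      unresolved <- c(unresolved, i)
    }
  }
  ## flat resolution: point each flat cell at an equal-elevation neighbour
  ## that already drains; deterministic via precedence order, acyclic because
  ## every assignment targets a previously resolved cell
  while (length(unresolved)) {
    progress <- FALSE
    still <- integer(0)
    for (i in unresolved) {
      nbs <- d8_neighbours(nr, nc, i)
      assigned <- FALSE
      for (k in seq_len(8L)) {
        nb <- nbs[k]
        if (is.na(nb) || is.na(z[nb])) next
        if (z[nb] <= z[i] && !is.na(dir[nb])) {
          dir[i] <- k; assigned <- TRUE; progress <- TRUE; break
        }
      }
      if (!assigned) still <- c(still, i)
    }
    if (!progress && length(still))
      stop("unresolvable flat remains after sink filling (", length(still),
           " cells)")
    unresolved <- still
  }
  structure(list(direction = dir, cell_size = filled_dem$cell_size,
                 origin = filled_dem$origin),
            class = "flow_grid")
}

## downstream cell index per cell (NA for outlets/nodata)
flow_targets <- function(flow) {
  dir <- flow$direction
  nr <- nrow(dir); nc <- ncol(dir)
  idx <- which(!is.na(dir) & dir > 0L)
  r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
  tgt <- rep(NA_integer_, length(dir))
  tgt[idx] <- (c + D8_DC[dir[idx]] - 1L) * nr + (r + D8_DR[dir[idx]])
  tgt
}

#' D8 flow accumulation
#'
#' Counts, for every cell, the number of cells draining through it including
#' itself (so drainage area = accumulation x cell_size^2). Computed in
#' topological order; a cycle in the direction field is an invariant breach
#' and raises an error.
#'
#' @param flow a \code{flow_grid} from \code{\link{flow_direction}}.
#' @return the \code{flow_grid} with an \code{accumulation} matrix added.
#' @export
flow_accumulation <- function(flow) {
  dir <- flow$direction
  n <- length(dir)
  tgt <- flow_targets(flow)
  acc <- ifelse(is.na(dir), NA_real_, 1)
  indeg <- integer(n)
  tt <- tgt[!is.na(tgt)]
  tb <- tabulate(tt, nbins = n)
  indeg <- tb
  queue <- which(!is.na(dir) & indeg == 0L)
  head <- 1L; processed <- 0L
  queue <- as.integer(queue)
  while (head <= length(queue)) {
    i <- queue[head]; head <- head + 1L; processed <- processed + 1L
    t0 <- tgt[i]
    if (!is.na(t0)) {
      acc[t0] <- acc[t0] + acc[i]
      indeg[t0] <- indeg[t0] - 1L
      if (indeg[t0] == 0L) queue[length(queue) + 1L] <- t0
    }
  }
  if (processed < sum(!is.na(dir)))
    stop("cycle detected in flow directions (acyclicity invariant breached)")
  flow$accumulation <- matrix(acc, nrow(dir), ncol(dir))
  flow
}

#' Extract the stream mask from accumulation
#'
#' @param flow a \code{flow_grid} with accumulation.
#' @param min_area minimum contributing area in km^2 (default 0.1, the
#'   drainage threshold used for the stream network).
#' @return logical matrix: cells whose drainage area >= min_area.
#' @export
extract_streams <- function(flow, min_area = 0.1) {
  if (min_area <= 0) stop("min_area must be positive")
  if (is.null(flow$accumulation)) stop("run flow_accumulation() first")
  area_km2 <- flow$accumulation * (flow$cell_size^2) / 1e6
  !is.na(area_km2) & area_km2 >= min_area
}

#' Segment the stream network into ~100 m reaches
#'
#' Stream cells are traced downstream into links (maximal paths between
#' heads, junctions and outlets); each link's polyline (cell centres, plus
#' the centre of the downstream target cell so no link is degenerate) is cut
#' into pieces of \code{target_length}; a trailing piece shorter than half
#' the target is merged into the previous reach. Every stream cell is
#' assigned to exactly one reach and the downstream topology is preserved.
#'
#' @param flow a \code{flow_grid} with accumulation.
#' @param mask logical stream mask from \code{\link{extract_streams}}.
#' @param filled_dem the filled DEM (for elevations).
#' @param target_length target reach length, metres (default 100).
#' @param min_last merge threshold for the trailing piece, metres
#'   (default \code{target_length / 2}).
#' @return a \code{stream_network}: list with a \code{reaches} data.frame
#'   (attributes filled by \code{\link{characterize_reaches}}), per-reach
#'   \code{geometry} (x,y matrices), per-reach \code{cells}, and the
#'   \code{flow} grid.
#' @export
segment_reaches <- function(flow, mask, filled_dem, target_length = 100,
                            min_last = target_length / 2) {
  if (!any(mask)) stop("stream mask is empty")
  dir <- flow$direction
  nr <- nrow(dir); nc <- ncol(dir); cs <- flow$cell_size
  tgt <- flow_targets(flow)
  scell <- which(mask)
  on_stream <- logical(length(dir)); on_stream[scell] <- TRUE
  ## stream inflow counts
  inflow <- integer(length(dir))
  for (i in scell) {
    t0 <- tgt[i]
    if (!is.na(t0) && on_stream[t0]) inflow[t0] <- inflow[t0] + 1L
  }
  heads <- scell[inflow[scell] == 0L]
  junctions <- scell[inflow[scell] >= 2L]
  starts <- sort(unique(c(heads, junctions)))
  grid_ref <- river_grid(matrix(0, nr, nc), cs, flow$origin)

  reach_rows <- list(); geom <- list(); cells_list <- list()
  link_of_start <- integer(0)       # first reach id per link start cell
  link_last <- integer(0)           # last reach id per link
  link_next_cell <- integer(0)      # downstream cell after link (NA if outlet)
  rid <- 0L
  for (li in seq_along(starts)) {
    s <- starts[li]
    path <- s
    cur <- s
    repeat {
      t0 <- tgt[cur]
      if (is.na(t0) || !on_stream[t0]) { nxt <- NA_integer_; break }
      if (inflow[t0] >= 2L) { nxt <- t0; break }   # next link starts there
      path <- c(path, t0); cur <- t0
    }
    verts <- path
    if (!is.na(nxt)) verts <- c(verts, nxt)
    xy <- grid_xy(grid_ref, verts)
    if (nrow(xy) == 1L) {
      ## single outlet cell with no downstream vertex: span the cell east-west
      ## so the reach has non-degenerate geometry of one cell length
      xy <- rbind(xy[1, ] - c(cs / 2, 0), xy[1, ] + c(cs / 2, 0))
    }
    steps <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
    chain <- c(0, cumsum(steps))
    total <- chain[length(chain)]
    npiece <- floor(total / target_length)
    rem <- total - npiece * target_length
    if (npiece == 0L) {
      cuts <- c(0, total)
    } else if (rem > min_last) {
      cuts <- c(seq(0, by = target_length, length.out = npiece + 1L), total)
    } else {                      # trailing piece <= min_last: merge back
      cuts <- seq(0, by = target_length, length.out = npiece + 1L)
      cuts[npiece + 1L] <- total
    }
    interp <- function(d) {  # point at chainage d
      if (total <= 0) return(xy[1, ])
      j <- findInterval(d, chain, rightmost.closed = TRUE)
      j <- min(max(j, 1L), length(chain) - 1L)
      f <- (d - chain[j]) / (chain[j + 1] - chain[j])
      xy[j, ] + f * (xy[j + 1, ] - xy[j, ])
    }
    first_rid_of_link <- rid + 1L
    for (k in seq_len(length(cuts) - 1L)) {
      rid <- rid + 1L
      d0 <- cuts[k]; d1 <- cuts[k + 1L]
      ## vertices of this piece: interpolated ends + interior cell centres
      inner <- which(chain > d0 & chain < d1)
      vxy <- rbind(interp(d0), xy[inner, , drop = FALSE], interp(d1))
      len <- max(d1 - d0, cs * 1e-6)
      ## cells whose centre chainage falls in [d0, d1); last piece inclusive
      owned_chain <- chain[seq_along(path)]
      sel <- owned_chain >= d0 & (owned_chain < d1 |
                                    (k == length(cuts) - 1L & owned_chain <= d1))
      own <- path[sel]
      ## a window between two diagonal cell centres can own no centre; fall
      ## back to the most downstream path cell at or before the reach end
      if (!length(own)) own <- path[max(which(owned_chain <= d1 + 1e-9))]
      cells_list[[rid]] <- own
      geom[[rid]] <- vxy
      mid <- interp((d0 + d1) / 2)
      reach_rows[[rid]] <- data.frame(
        reach_id = rid, link = li, length_m = len,
        up_x = vxy[1, 1], up_y = vxy[1, 2],
        down_x = vxy[nrow(vxy), 1], down_y = vxy[nrow(vxy), 2],
        mid_x = mid[1], mid_y = mid[2],
        downstream = if (k < length(cuts) - 1L) rid + 1L else NA_integer_)
    }
    link_of_start[li] <- first_rid_of_link
    link_last[li] <- rid
    link_next_cell[li] <- if (exists("nxt") && !is.na(nxt)) nxt else NA_integer_
  }
  reaches <- do.call(rbind, reach_rows)
  ## link the last reach of each link to the first reach of the downstream link
  start_lookup <- stats::setNames(link_of_start, starts)
  for (li in seq_along(starts)) {
    nxt <- link_next_cell[li]
    if (!is.na(nxt))
      reaches$downstream[link_last[li]] <- start_lookup[[as.character(nxt)]]
  }
  ## basin id: connected component by following downstream links
  basin <- integer(nrow(reaches))
  find_root <- function(r) { while (!is.na(reaches$downstream[r]))
    r <- reaches$downstream[r]; r }
  roots <- vapply(seq_len(nrow(reaches)), find_root, integer(1))
  basin <- as.integer(factor(roots))
  reaches$basin <- basin
  structure(list(reaches = reaches, geometry = geom, cells = cells_list,
                 flow = flow, mask = mask, cell_size = cs,
                 filled_dem = filled_dem),
            class = "stream_network")
}

#' @export
print.stream_network <- function(x, ...) {
  cat(sprintf("<stream_network> %d reaches, %d basins, cell %g m\n",
              nrow(x$reaches), length(unique(x$reaches$basin)), x$cell_size))
  invisible(x)
}

#' Strahler stream order per reach
#'
#' Headwater reaches are order 1; where the two largest incoming orders are
#' equal the downstream order increments, otherwise the maximum propagates.
#' Confluences of more than two are combined pairwise in descending order.
#'
#' @param network a \code{stream_network}.
#' @return integer vector of orders aligned with \code{network$reaches}.
#' @export
strahler_order <- function(network) {
  r <- network$reaches
  n <- nrow(r)
  ups <- split(seq_len(n), factor(r$downstream, levels = seq_len(n)))
  order_v <- rep(NA_integer_, n)
  indeg <- vapply(ups, length, integer(1))
  queue <- which(indeg == 0L); head <- 1L
  remaining <- indeg
  while (head <= length(queue)) {
    i <- queue[head]; head <- head + 1L
    up <- ups[[i]]
    if (length(up) == 0L) order_v[i] <- 1L
    else {
      o <- sort(order_v[up], decreasing = TRUE)
      cur <- o[1]
      for (k in seq_along(o)[-1]) cur <- if (o[k] == cur) cur + 1L
                                         else max(cur, o[k])
      order_v[i] <- cur
    }
    d <- r$downstream[i]
    if (!is.na(d)) {
      remaining[d] <- remaining[d] - 1L
      if (remaining[d] == 0L) queue[length(queue) + 1L] <- d
    }
  }
  order_v
}

## Horn (3x3) aspect at one cell: degrees clockwise from north of the
## downslope direction; edge rows/cols replicated
horn_aspect <- function(dem, idx) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z); cs <- dem$cell_size
  r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
  rr <- pmin(pmax(r + c(-1L, 0L, 1L), 1L), nr)
  cc <- pmin(pmax(c + c(-1L, 0L, 1L), 1L), nc)
  w <- z[rr, cc]
  dzdx <- ((w[1, 3] + 2 * w[2, 3] + w[3, 3]) -
             (w[1, 1] + 2 * w[2, 1] + w[3, 1])) / (8 * cs)
  dzdy <- ((w[1, 1] + 2 * w[1, 2] + w[1, 3]) -
             (w[3, 1] + 2 * w[3, 2] + w[3, 3])) / (8 * cs)   # + north
  if (dzdx == 0 && dzdy == 0) return(NA_real_)               # flat: undefined
  (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
}

#' Valley confinement index
#'
#' 1 - (fraction of cells within \code{search_radius} of the reach midpoint
#' whose elevation is <= reach elevation + \code{relief_threshold}); 0 on a
#' broad open valley floor, near 1 in a slot canyon. The window is clipped
#' at the grid edge. The formula is a documented stand-in: the source method
#' names only a confinement "index".
#'
#' @param network a \code{stream_network}.
#' @param search_radius metres (default 300; must be >= one cell).
#' @param relief_threshold metres of relief counted as "valley floor"
#'   (default 10).
#' @return numeric vector in [0, 1] per reach.
#' @export
valley_confinement <- function(network, search_radius = 300,
                               relief_threshold = 10) {
  dem <- network$filled_dem
  if (search_radius < dem$cell_size)
    stop("search_radius must be at least one cell size")
  z <- dem$values; nr <- nrow(z); nc <- ncol(z); cs <- dem$cell_size
  half <- ceiling(search_radius / cs) + 1L
  vapply(seq_len(nrow(network$reaches)), function(i) {
    mid <- c(network$reaches$mid_x[i], network$reaches$mid_y[i])
    ci <- grid_cell_at(dem, mid[1], mid[2])
    relev <- z[ci]
    r <- (ci - 1L) %% nr + 1L; c <- (ci - 1L) %/% nr + 1L
    rs <- max(1L, r - half):min(nr, r + half)
    cols <- max(1L, c - half):min(nc, c + half)
    sub <- z[rs, cols, drop = FALSE]
    idx <- as.vector(outer(rs, (cols - 1L) * nr, "+"))
    cxy <- grid_xy(dem, idx)
    d <- sqrt((cxy[, 1] - mid[1])^2 + (cxy[, 2] - mid[2])^2)
    keep <- d <= search_radius & !is.na(as.vector(sub))
    vals <- as.vector(sub)[keep]
    1 - mean(vals <= relev + relief_threshold)
  }, numeric(1))
}

#' Network distances to outlet and headwaters
#'
#' \code{dist_downstream}: summed reach lengths from each reach to its basin
#' outlet, inclusive of the reach itself. \code{dist_upstream}: the longest
#' summed path from the reach up to any headwater, inclusive. Both in km.
#'
#' @param network a \code{stream_network}.
#' @return data.frame(dist_downstream, dist_upstream) in km.
#' @export
network_distances <- function(network) {
  r <- network$reaches
  n <- nrow(r)
  len <- r$length_m
  down <- rep(NA_real_, n); up <- rep(NA_real_, n)
  ups <- split(seq_len(n), factor(r$downstream, levels = seq_len(n)))
  ## topological order: headwaters first
  order_topo <- integer(0)
  remaining <- vapply(ups, length, integer(1))
  queue <- which(remaining == 0L); head <- 1L
  while (head <= length(queue)) {
    i <- queue[head]; head <- head + 1L
    order_topo <- c(order_topo, i)
    d <- r$downstream[i]
    if (!is.na(d)) { remaining[d] <- remaining[d] - 1L
      if (remaining[d] == 0L) queue[length(queue) + 1L] <- d }
  }
  for (i in order_topo) {
    u <- ups[[i]]
    up[i] <- len[i] + if (length(u)) max(up[u]) else 0
  }
  for (i in rev(order_topo)) {
    d <- r$downstream[i]
    down[i] <- len[i] + if (!is.na(d)) down[d] else 0
  }
  data.frame(dist_downstream = down / 1000, dist_upstream = up / 1000)
}

build_rev_adj <- function(flow) {
  tgt <- flow_targets(flow)
  n <- length(flow$direction)
  src <- which(!is.na(tgt))
  split(src, factor(tgt[src], levels = seq_len(n)))
}

catchment_bfs <- function(seeds, rev_adj, n) {
  inset <- logical(n); inset[seeds] <- TRUE
  queue <- as.integer(seeds); head <- 1L
  while (head <= length(queue)) {
    i0 <- queue[head]; head <- head + 1L
    for (s in rev_adj[[i0]]) if (!inset[s]) {
      inset[s] <- TRUE; queue[length(queue) + 1L] <- s
    }
  }
  which(inset)
}

#' Delineate the catchment of a reach
#'
#' All cells whose flow path passes through any cell of the reach (reverse
#' breadth-first search on the D8 direction graph, reach cells included).
#' Catchments nest downstream.
#'
#' @param network a \code{stream_network}.
#' @param reach_id reach identifier.
#' @return integer vector of column-major cell indices.
#' @export
delineate_catchment <- function(network, reach_id) {
  i <- match(reach_id, network$reaches$reach_id)
  if (is.na(i)) stop("unknown reach_id: ", reach_id)
  catchment_bfs(network$cells[[i]], build_rev_adj(network$flow),
                length(network$flow$direction))
}

#' Catchments of every reach
#'
#' @param network a \code{stream_network}.
#' @return list of cell-index vectors, one per reach, in reach order.
#' @export
catchment_sets <- function(network) {
  rev_adj <- build_rev_adj(network$flow)
  n <- length(network$flow$direction)
  lapply(network$cells, catchment_bfs, rev_adj = rev_adj, n = n)
}

#' Geometry and terrain attributes for every reach
#'
#' Fills the reach table with: drainage_area (km^2, accumulation at the most
#' downstream reach cell x cell^2), gradient (%, drop over path length,
#' floored at 0), sinuosity (path length / endpoint chord, 1 if endpoints
#' coincide), aspect (Horn method at the midpoint cell, degrees from north),
#' elevation (filled DEM at midpoint), strahler order, valley confinement
#' and the up-/downstream network distances.
#'
#' @param network a \code{stream_network}.
#' @param search_radius,relief_threshold see \code{\link{valley_confinement}}.
#' @return the network with a completed \code{reaches} table.
#' @export
characterize_reaches <- function(network, search_radius = 300,
                                 relief_threshold = 10) {
  r <- network$reaches
  dem <- network$filled_dem
  acc <- network$flow$accumulation
  cs <- network$cell_size
  n <- nrow(r)
  grad <- sinu <- asp <- elev <- area <- numeric(n)
  for (i in seq_len(n)) {
    vxy <- network$geometry[[i]]
    segs <- sqrt(diff(vxy[, 1])^2 + diff(vxy[, 2])^2)
    plen <- sum(segs)
    if (plen <= 0) stop("degenerate zero-length reach geometry (reach ",
                        r$reach_id[i], ")")
    chord <- sqrt((vxy[1, 1] - vxy[nrow(vxy), 1])^2 +
                    (vxy[1, 2] - vxy[nrow(vxy), 2])^2)
    sinu[i] <- if (chord == 0) 1 else max(1, plen / chord)
    ## clamp lookups: synthetic end vertices of boundary outlet cells can
    ## poke half a cell beyond the grid edge
    cell_clamped <- function(x, y) {
      eps <- dem$cell_size / 100
      xr <- dem$origin[1] + c(eps, ncol(dem$values) * dem$cell_size - eps)
      yr <- dem$origin[2] + c(eps, nrow(dem$values) * dem$cell_size - eps)
      grid_cell_at(dem, min(max(x, xr[1]), xr[2]), min(max(y, yr[1]), yr[2]))
    }
    zu <- dem$values[cell_clamped(vxy[1, 1], vxy[1, 2])]
    zd <- dem$values[cell_clamped(vxy[nrow(vxy), 1], vxy[nrow(vxy), 2])]
    grad[i] <- max(0, 100 * (zu - zd) / plen)
    mid_cell <- grid_cell_at(dem, r$mid_x[i], r$mid_y[i])
    asp[i] <- horn_aspect(dem, mid_cell)
    elev[i] <- dem$values[mid_cell]
    dcell <- network$cells[[i]]
    dcell <- dcell[length(dcell)]
    area[i] <- acc[dcell] * cs^2 / 1e6
  }
  r$gradient <- grad; r$sinuosity <- sinu; r$aspect <- asp
  r$elevation <- elev; r$drainage_area <- area
  r$strahler <- strahler_order(network)
  r$valley_confinement <- valley_confinement(network, search_radius,
                                             relief_threshold)
  nd <- network_distances(network)
  r$dist_downstream <- nd$dist_downstream
  r$dist_upstream <- nd$dist_upstream
  network$reaches <- r
  network
}

#' Build a characterized stream network from a DEM
#'
#' Convenience driver: fill sinks, route D8 flow, accumulate, threshold the
#' drainage area, segment ~100 m reaches and attach all attributes.
#'
#' @param dem an elevation \code{river_grid}.
#' @param min_area stream initiation threshold, km^2 (default 0.1).
#' @param target_length reach target length, metres (default 100).
#' @param search_radius,relief_threshold confinement parameters.
#' @return a characterized \code{stream_network}.
#' @export
build_stream_network <- function(dem, min_area = 0.1, target_length = 100,
                                 search_radius = 300, relief_threshold = 10) {
  filled <- fill_sinks(dem)
  flow <- flow_accumulation(flow_direction(filled))
  mask <- extract_streams(flow, min_area)
  net <- segment_reaches(flow, mask, filled, target_length)
  characterize_reaches(net, search_radius, relief_threshold)
}
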