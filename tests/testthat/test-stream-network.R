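## helper: plane tilted so flow runs due west, metres
tilted_plane <- function(nr = 16, nc = 16, cell = 100, slope = 0.02) {
  river_grid(matrix(rep((seq_len(nc) - 1) * cell * slope, each = nr),
                    nr, nc), cell)
}

test_that("fill_sinks is identity on pitless terrain and fills pits to the
           pour point", {
  dem <- tilted_plane()
  expect_equal(fill_sinks(dem)$values, dem$values)
  ## single 1-cell pit raised exactly to its lowest pour point
  z <- dem$values
  z[8, 8] <- z[8, 8] - 5
  pour <- min(z[7:9, 7:9][-5])
  f <- fill_sinks(river_grid(z, 100))
  expect_equal(f$values[8, 8], pour)
  expect_true(all(f$values >= z))               # filled >= original
  expect_error(fill_sinks(river_grid(matrix(NA_real_, 4, 4), 1)), "nodata")
})

test_that("random DEMs have zero pits after filling (oracle scan)", {
  for (seed in 1:8) {
    set.seed(seed)
    z <- matrix(rnorm(32 * 32, sd = 10), 32, 32)
    f <- fill_sinks(river_grid(z, 30))
    expect_length(oracle_find_pits(f$values), 0)
    expect_true(all(f$values >= z))
  }
})

test_that("flow_direction matches exhaustive steepest descent", {
  ## symmetric ridge: two opposite direction fields
  z <- outer(rep(0, 9), c(4:0, 1:4), "+")
  fd <- flow_direction(fill_sinks(river_grid(z, 100)))
  ## z rises away from centre col 5 (values 4..0..4): symmetric halves give
  ## two opposite direction fields, E (code 1) left and W (code 5) right
  expect_true(all(fd$direction[, 1:4] == 1L))
  expect_true(all(fd$direction[, 6:9] == 5L))
  ## random grids against the brute-force oracle
  for (seed in 1:10) {
    set.seed(seed)
    z <- matrix(rnorm(25, sd = 5), 5, 5)
    f <- fill_sinks(river_grid(z, 50))
    fd <- flow_direction(f)
    for (r in 1:5) for (c in 1:5) {
      want <- oracle_d8_cell(f$values, r, c, 50)
      got <- fd$direction[r, c]
      if (is.na(want)) {
        ## no strictly lower neighbour: outlet (boundary) or resolved flat
        expect_true(got == 0L || f$values[r + c(0,1,1,1,0,-1,-1,-1)[got],
                                          c + c(1,1,0,-1,-1,-1,0,1)[got]] <=
                      f$values[r, c])
      } else expect_identical(got, want)
    }
  }
})

test_that("flow_accumulation counts upstream cells exactly", {
  ## 1 x 3 strip flowing east has accumulation 1, 2, 3
  z <- matrix(c(3, 2, 1), 1, 3)
  fl <- flow_accumulation(flow_direction(river_grid(z, 100)))
  expect_equal(as.vector(fl$accumulation), c(1, 2, 3))
  ## oracle equivalence + outlet conservation on random grids
  for (seed in 1:12) {
    set.seed(seed)
    n <- if (seed <= 6) 8L else 12L
    z <- matrix(rnorm(n * n, sd = 8), n, n)
    f <- fill_sinks(river_grid(z, 30))
    fl <- flow_accumulation(flow_direction(f))
    expect_equal(fl$accumulation, oracle_accumulation(fl$direction, 30))
    expect_identical(sum(fl$accumulation[fl$direction == 0L]),
                     as.numeric(n * n))
  }
})

test_that("extract_streams applies the drainage-area threshold", {
  dem <- tilted_plane(20, 20, cell = 30)
  fl <- flow_accumulation(flow_direction(fill_sinks(dem)))
  mask <- extract_streams(fl, min_area = 0.1)
  ## brute force: area = acc * 0.0009 km2 >= 0.1 -> acc >= 111.11
  expect_identical(mask, fl$accumulation * 30^2 / 1e6 >= 0.1)
  expect_identical(sum(mask), sum(fl$accumulation >= 0.1e6 / 900))
  ## threshold larger than the basin: empty mask
  expect_false(any(extract_streams(fl, min_area = 1e6)))
  expect_error(extract_streams(fl, min_area = 0), "positive")
  ## 100 m cells: 0.01 km2 each, so threshold 0.1 km2 is accumulation >= 10
  dem2 <- tilted_plane(16, 16, cell = 100)
  fl2 <- flow_accumulation(flow_direction(fill_sinks(dem2)))
  expect_identical(extract_streams(fl2, 0.1), fl2$accumulation >= 10)
})

test_that("segment_reaches cuts links into ~100 m reaches with the merge
           rule", {
  ## single straight west-flowing link: 1 x 12 grid of 100 m cells, mask
  ## covering 11 stream cells -> polyline length picked by the mask shape
  z <- matrix(seq(12, 1), 1, 12) * 5
  dem <- river_grid(z, 100)
  fl <- flow_accumulation(flow_direction(fill_sinks(dem)))
  mask <- matrix(FALSE, 1, 12); mask[1, 2:12] <- TRUE
  net <- segment_reaches(fl, mask, fill_sinks(dem), target_length = 100)
  ## head at col 2, traced through col 12 (outlet): 10 steps of 100 m
  expect_equal(nrow(net$reaches), 10)
  expect_equal(net$reaches$length_m, rep(100, 10))
  ## topology is a single chain ending at the outlet
  expect_identical(sum(is.na(net$reaches$downstream)), 1L)
  ## 1050 m link: last segment of 50 m merges -> 10 reaches, last 150 m
  ## (1 x 11 strip of 105 m cells, all masked: 10 steps of 105 m)
  z3 <- matrix(seq(11, 1), 1, 11) * 5
  dem3 <- river_grid(z3, 105)
  fl3 <- flow_accumulation(flow_direction(fill_sinks(dem3)))
  mask3 <- matrix(TRUE, 1, 11)
  net3 <- segment_reaches(fl3, mask3, fill_sinks(dem3), target_length = 100)
  ## total polyline 10 x 105 = 1050 m
  expect_equal(sum(net3$reaches$length_m), 1050)
  expect_equal(nrow(net3$reaches), 10)
  expect_equal(net3$reaches$length_m[10], 150)
  ## every stream cell assigned to exactly one reach
  expect_setequal(unlist(net3$cells), which(mask3))
  expect_identical(sum(lengths(net3$cells)), sum(mask3))
})

test_that("strahler order follows the junction rules", {
  ## Y network on a 7x7 grid: two headwaters joining then flowing west
  ## build explicit direction grid: row4 flows west; two tributaries flow
  ## into (4,5) from NE and SE
  dirm <- matrix(NA_integer_, 7, 7)
  dirm[4, 1] <- 0L
  dirm[4, 2:5] <- 5L                 # west
  dirm[3, 6] <- 4L                   # SW into (4,5)
  dirm[2, 7] <- 4L                   # SW into (3,6)
  dirm[5, 6] <- 6L                   # NW into (4,5)
  dirm[6, 7] <- 6L                   # NW into (5,6)
  fl <- structure(list(direction = dirm, cell_size = 100, origin = c(0, 0)),
                  class = "flow_grid")
  fl <- flow_accumulation(fl)
  mask <- !is.na(dirm)
  dem <- river_grid(matrix(as.numeric(col(dirm) + abs(4 - row(dirm))), 7, 7)
                    * 2, 100)
  net <- segment_reaches(fl, mask, dem, target_length = 100)
  ord <- strahler_order(net)
  r <- net$reaches
  ## headwater reaches are order 1; the mainstem below the junction is 2
  expect_true(all(ord >= 1))
  outlet_reach <- which(is.na(r$downstream))
  expect_identical(ord[outlet_reach], 2L)
  ## strahler non-decreasing downstream on every path
  for (i in seq_len(nrow(r))) {
    d <- r$downstream[i]
    if (!is.na(d)) expect_gte(ord[d], ord[i])
  }
  ## single path network: all order 1
  z <- matrix(seq(8, 1), 1, 8)
  flp <- flow_accumulation(flow_direction(river_grid(z, 100)))
  netp <- segment_reaches(flp, matrix(TRUE, 1, 8), river_grid(z, 100), 100)
  expect_true(all(strahler_order(netp) == 1L))
})

test_that("reach geometry attributes: gradient, sinuosity, elevation", {
  ## straight 1000 m link dropping 2 m per 100 m reach -> gradient 2 %
  z <- matrix(seq(0, 22, by = 2)[12:1], 1, 12)
  dem <- river_grid(z, 100)
  fl <- flow_accumulation(flow_direction(fill_sinks(dem)))
  mask <- matrix(TRUE, 1, 12)
  net <- characterize_reaches(segment_reaches(fl, mask, dem, 100))
  r <- net$reaches
  expect_equal(r$sinuosity, rep(1, nrow(r)))
  inner <- which(!is.na(r$downstream))
  expect_equal(r$gradient[inner], rep(2, length(inner)))
  ## gradient is floored at zero on rising geometry
  expect_true(all(r$gradient >= 0))
  ## network distances on the chain: headwater reach reaches the outlet
  ## after the full chain length
  expect_equal(max(r$dist_downstream), sum(r$length_m) / 1000)
  expect_equal(r$dist_upstream[which(is.na(r$downstream))],
               sum(r$length_m) / 1000)
  ## semicircular polyline has sinuosity pi/2 (pure geometry check)
  theta <- seq(0, pi, length.out = 200)
  semi <- cbind(50 * cos(theta), 50 * sin(theta))
  plen <- sum(sqrt(diff(semi[, 1])^2 + diff(semi[, 2])^2))
  chord <- sqrt(sum((semi[1, ] - semi[200, ])^2))
  expect_equal(plen / chord, pi / 2, tolerance = 1e-3)
})

test_that("valley confinement separates plains from canyons", {
  ## flat plain -> 0
  flat <- river_grid(matrix(10, 21, 21), 100)
  fl <- flow_accumulation(flow_direction(fill_sinks(
    river_grid(matrix(rep(seq(21, 1), each = 21), 21, 21), 100))))
  mask <- matrix(FALSE, 21, 21); mask[11, ] <- TRUE
  net <- segment_reaches(fl, mask, flat, 100)
  net$filled_dem <- flat
  expect_equal(valley_confinement(net, 300, 10),
               rep(0, nrow(net$reaches)))
  ## slot canyon: walls 500 m above the channel -> index near 1
  canyon <- matrix(500, 21, 21); canyon[11, ] <- 0
  net$filled_dem <- river_grid(canyon, 100)
  vc <- valley_confinement(net, 300, 10)
  expect_true(all(vc > 0.7))
  ## brute-force window count on a V-valley of known half width
  v <- river_grid(matrix(abs(row(matrix(0, 21, 21)) - 11) * 50, 21, 21), 100)
  net$filled_dem <- v
  vc2 <- valley_confinement(net, 300, 10)
  i <- 3   # an interior reach
  mid <- c(net$reaches$mid_x[i], net$reaches$mid_y[i])
  ## enumerate cells within 300 m of the midpoint
  xy <- grid_xy(v)
  d <- sqrt((xy[, 1] - mid[1])^2 + (xy[, 2] - mid[2])^2)
  cells <- which(d <= 300)
  relev <- v$values[grid_cell_at(v, mid[1], mid[2])]
  expect_equal(vc2[i], 1 - mean(v$values[cells] <= relev + 10))
})

test_that("catchments match accumulation and nest downstream", {
  cfg <- tiny_world()
  net <- build_stream_network(make_dem(cfg))
  r <- net$reaches
  catch <- catchment_sets(net)
  ## catchment area at a reach equals the drainage-area attribute
  for (i in c(1L, nrow(r) %/% 2L, nrow(r))) {
    cells <- delineate_catchment(net, r$reach_id[i])
    expect_setequal(cells, catch[[i]])
    expect_equal(length(cells) * net$cell_size^2 / 1e6,
                 r$drainage_area[i], tolerance = 1e-12)
  }
  ## nesting along downstream chains
  for (i in seq_len(min(nrow(r), 40L))) {
    d <- r$downstream[i]
    if (!is.na(d)) expect_true(all(catch[[i]] %in% catch[[d]]))
  }
})
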