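test_that("haversine distances match closed forms", {
  d <- haversine_km(c(7, 7), c(45, 45), c("a", "b"))
  expect_equal(unname(d["a", "b"]), 0)
  anti <- haversine_km(c(0, 180), c(0, 0), c("a", "b"))
  expect_equal(unname(anti["a", "b"]), pi * 6371, tolerance = 1e-6)
  set.seed(4)
  r <- haversine_km(stats::runif(5, -180, 180), stats::runif(5, -60, 60))
  expect_equal(unclass(r), t(unclass(r)), ignore_attr = TRUE)
  expect_error(haversine_km(c(0, NA), c(0, 0), c("a", "b")), "b")
})

test_that("Delaunay connectivity matches the empty-circumcircle oracle", {
  tri <- data.frame(site_id = c("a", "b", "c"), lon = c(0, 1, 0.5), lat = c(0, 0, 1))
  net <- build_connectivity(tri)
  expect_equal(nrow(net$edges), 3)
  # convex quadrilateral (not cocircular): 4 hull edges + 1 diagonal
  quad <- data.frame(site_id = letters[1:4],
                     lon = c(0, 2, 2.2, 0.3), lat = c(0, 0.1, 1.9, 2.2))
  expect_equal(nrow(build_connectivity(quad)$edges), 5)
  # random 20-site set against the O(n^4) oracle
  set.seed(9)
  pts <- data.frame(site_id = sprintf("s%02d", 1:20),
                    lon = stats::runif(20, 0, 10), lat = stats::runif(20, 40, 50))
  net20 <- build_connectivity(pts)
  xy <- cbind(pts$lon * cos(mean(pts$lat) * pi / 180), pts$lat)
  want <- delaunay_oracle(xy)
  got <- cbind(match(net20$edges$from, pts$site_id),
               match(net20$edges$to, pts$site_id))
  got <- t(apply(got, 1, sort))
  expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))

  expect_error(build_connectivity(tri[1:2, ]), ">= 3")
  line <- data.frame(site_id = c("a", "b", "c"), lon = c(0, 1, 2), lat = c(0, 0, 0))
  expect_error(build_connectivity(line), "collinear")
  dup <- data.frame(site_id = c("a", "b", "c", "d"),
                    lon = c(0, 1, 0.5, 0.5), lat = c(0, 0, 1, 1))
  expect_warning(build_connectivity(dup), "jittered")
})

test_that("edge midpoints carry the mean cross-site distance", {
  coords <- data.frame(site_id = c("A", "B", "C"), lon = c(0, 1, 0.5), lat = c(0, 0, 1))
  net <- build_connectivity(coords)
  # one sample per site
  ids <- c("x", "y", "z")
  d <- matrix(0.04, 3, 3, dimnames = list(ids, ids)); diag(d) <- 0
  mp <- edge_midpoint_values(net, dist_matrix(d), stats::setNames(c("A", "B", "C"), ids))
  expect_equal(mp$value, rep(0.04, 3))
  expect_equal(mp$lon[mp$from == "A" & mp$to == "B"], 0.5)
  # 2x2 samples with distances {1,2,3,4} -> mean 2.5
  ids2 <- c("a1", "a2", "b1", "b2")
  m <- matrix(0, 4, 4, dimnames = list(ids2, ids2))
  m["a1", "b1"] <- 1; m["a1", "b2"] <- 2; m["a2", "b1"] <- 3; m["a2", "b2"] <- 4
  m["a1", "a2"] <- 9; m["b1", "b2"] <- 9
  m <- m + t(m)
  map2 <- stats::setNames(c("A", "A", "B", "B"), ids2)
  coords2 <- data.frame(site_id = c("A", "B", "C"), lon = c(0, 1, 0.5), lat = c(0, 0, 1))
  net2 <- build_connectivity(coords2)
  expect_warning(
    mp2 <- edge_midpoint_values(net2, dist_matrix(m), map2),
    "dropped")   # edges to site C have no samples
  expect_equal(mp2$value[mp2$from == "A" & mp2$to == "B"], 2.5)
})

test_that("residualizing removes a perfect linear trend and centres residuals", {
  coords <- data.frame(site_id = sprintf("S%d", 1:4),
                       lon = c(0, 3, 1, 4), lat = c(0, 0.5, 2, 2.5))
  net <- build_connectivity(coords)
  gd <- haversine_km(coords$lon, coords$lat, coords$site_id)
  mp <- data.frame(lon = net$edges$mid_lon, lat = net$edges$mid_lat,
                   value = NA_real_, from = net$edges$from, to = net$edges$to)
  pred <- gd[cbind(mp$from, mp$to)]
  mp$value <- 2 + 0.01 * pred          # perfectly linear
  res <- residualize(mp, coords)
  expect_equal(res$value, rep(0, nrow(mp)), tolerance = 1e-10)
  # noisy values: residuals sum to zero, and match the normal equations
  set.seed(2)
  mp$value <- 2 + 0.01 * pred + stats::rnorm(nrow(mp), 0, 0.5)
  res2 <- residualize(mp, coords)
  expect_equal(sum(res2$value), 0, tolerance = 1e-9)
  X <- cbind(1, pred)
  beta <- solve(t(X) %*% X, t(X) %*% mp$value)
  expect_equal(res2$value, as.vector(mp$value - X %*% beta), tolerance = 1e-9)
})

test_that("IDW surfaces are convex, exact at data points, and match direct sums", {
  set.seed(5)
  pts <- data.frame(lon = stats::runif(10, 0, 5), lat = stats::runif(10, 40, 44),
                    value = stats::runif(10, 0, 3))
  s <- idw_surface(pts, a = 2, grid_cols = 25)
  expect_true(all(s$values >= min(pts$value) - 1e-12, na.rm = TRUE))
  expect_true(all(s$values <= max(pts$value) + 1e-12, na.rm = TRUE))
  # probe five grid nodes against the direct formula
  cc <- phylochem:::surface_cell_centers(s)
  lat0 <- mean(pts$lat)
  probes <- cbind(sample(seq_len(nrow(s$values)), 5), sample(seq_len(ncol(s$values)), 5))
  for (k in 1:5) {
    i <- probes[k, 1]; j <- probes[k, 2]
    if (s$mask[i, j]) next
    dx <- (cc$lon[j] - pts$lon) * cos(lat0 * pi / 180)
    dy <- cc$lat[i] - pts$lat
    w <- 1 / (dx^2 + dy^2)
    expect_equal(s$values[i, j], sum(w * pts$value) / sum(w), tolerance = 1e-10)
  }
  # constant input -> constant surface
  pts$value <- 2.5
  sc <- idw_surface(pts, grid_cols = 10)
  expect_true(all(abs(sc$values - 2.5) < 1e-12, na.rm = TRUE))
  # symmetric two-point case: equidistant node takes the midpoint value
  two <- data.frame(lon = c(0, 1), lat = c(0, 0), value = c(0, 10))
  st <- idw_surface(two, grid_cols = 11, margin = 0, mask_hull = FALSE)
  mid <- st$values[, 6]
  expect_true(any(abs(mid - 5) < 1e-6))
  expect_error(idw_surface(two[0, ]), "empty")
})

test_that("large exponents converge IDW to nearest-neighbour values", {
  set.seed(8)
  pts <- data.frame(lon = stats::runif(6, 0, 4), lat = stats::runif(6, 40, 43),
                    value = stats::runif(6))
  s <- idw_surface(pts, a = 50, grid_cols = 15, mask_hull = FALSE)
  cc <- phylochem:::surface_cell_centers(s)
  lat0 <- mean(pts$lat)
  for (k in 1:8) {
    i <- sample(nrow(s$values), 1); j <- sample(ncol(s$values), 1)
    dx <- (cc$lon[j] - pts$lon) * cos(lat0 * pi / 180)
    dy <- cc$lat[i] - pts$lat
    nn <- which.min(dx^2 + dy^2)
    d2 <- sort(dx^2 + dy^2)
    if (d2[2] / d2[1] < 1.5) next    # skip near-ties where convergence is slow
    expect_equal(s$values[i, j], pts$value[nn], tolerance = 1e-3)
  }
})

test_that("surfaces are equivariant under coordinate translation", {
  set.seed(12)
  pts <- data.frame(lon = stats::runif(8, 0, 3), lat = stats::runif(8, 41, 43),
                    value = stats::runif(8))
  s1 <- idw_surface(pts, grid_cols = 12)
  # longitude shifts leave the planar geometry untouched; latitude shifts
  # change the projection's cos(lat0) scale and are only approximately so
  pts2 <- pts; pts2$lon <- pts2$lon + 5
  s2 <- idw_surface(pts2, grid_cols = 12)
  expect_equal(s2$values, s1$values, tolerance = 1e-8)
  expect_equal(s2$origin, s1$origin + c(5, 0), tolerance = 1e-8)
})

test_that("diversity surfaces interpolate group values at barycenters", {
  st <- validate_sample_table(data.frame(
    id = paste0("i", 1:6),
    site_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    lat = c(40, 41, 40.5, 45, 46, 45.5), lon = c(0, 1, 0.5, 10, 11, 10.5),
    geo_group = rep(c("G1", "G2"), each = 3),
    colour_label = "m"))
  bary <- group_barycenters(st)
  expect_equal(nrow(bary), 2)
  expect_equal(bary$lon[bary$geo_group == "G1"], 0.5)
  s <- diversity_surface(c(G1 = 0, G2 = 0.01), bary, grid_cols = 12)
  expect_true(all(s$values >= 0 - 1e-15 & s$values <= 0.01 + 1e-15, na.rm = TRUE))
  # single valid group: constant surface; NA group excluded with warning
  expect_warning(s2 <- diversity_surface(c(G1 = 0.004, G2 = NA), bary, grid_cols = 8),
                 "excluded")
  expect_true(all(abs(s2$values - 0.004) < 1e-12, na.rm = TRUE))
  expect_error(suppressWarnings(diversity_surface(c(G1 = NA, G2 = NA), bary)),
               "no group")
})
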