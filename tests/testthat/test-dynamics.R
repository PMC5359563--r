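test_that("zone components match hand counts on tiny fixtures", {
  # identical maps: nothing moves
  m <- categorical_map(matrix(c(1L, 2L, 1L, 2L), 2, 2), timestamp = 2000)
  m2 <- m; m2$timestamp <- 2013
  zg <- matrix(1L, 2, 2)
  comp <- zone_change_components(m, m2, zg)
  expect_true(all(comp$increase == 0 & comp$decrease == 0))
  expect_equal(sum(comp$nochange), 4)

  # 2-cell zone [1,1] -> [1,2]
  m1 <- categorical_map(matrix(c(1L, 1L), 1, 2), timestamp = 2000)
  m2 <- categorical_map(matrix(c(1L, 2L), 1, 2), timestamp = 2013)
  comp <- zone_change_components(m1, m2, matrix(1L, 1, 2))
  expect_equal(comp$nochange[comp$class == "class_1"], 1)
  expect_equal(comp$decrease[comp$class == "class_1"], 1)
  expect_equal(comp$increase[comp$class == "class_2"], 1)
  expect_equal(sum(comp$increase), sum(comp$decrease))
})

test_that("zone components equal the per-cell loop oracle on quadrant zones", {
  pair <- rand_map_pair(100, 100, seed = 21)
  zg <- matrix(0L, 100, 100)
  zg[1:50, 1:50] <- 1L; zg[1:50, 51:100] <- 2L
  zg[51:100, 1:50] <- 3L; zg[51:100, 51:100] <- 4L
  comp <- zone_change_components(pair$m1, pair$m2, zg)
  oracle <- oracle_zone_components(pair$m1, pair$m2, zg, 1:6, 1:4)
  for (z in 1:4) for (k in 1:6) {
    row <- comp[comp$zone_id == z & comp$class == paste0("class_", k), ]
    expect_equal(row$increase, unname(oracle$increase[z, k]))
    expect_equal(row$decrease, unname(oracle$decrease[z, k]))
    expect_equal(row$nochange, unname(oracle$nochange[z, k]))
  }
})

test_that("summing zone components over all zones reproduces the whole-map budget", {
  pair <- rand_map_pair(60, 60, seed = 8)
  zones <- generate_zones(pair$m1, 9, seed = 4)
  comp <- zone_change_components(pair$m1, pair$m2, zones)
  counts <- cross_tabulate(pair$m1, pair$m2, basis = "cells")
  b <- change_budget(counts)
  agg_inc <- tapply(comp$increase, comp$class, sum)
  agg_dec <- tapply(comp$decrease, comp$class, sum)
  agg_per <- tapply(comp$nochange, comp$class, sum)
  expect_equal(as.numeric(agg_inc[b$class]), b$gain)
  expect_equal(as.numeric(agg_dec[b$class]), b$loss)
  expect_equal(as.numeric(agg_per[b$class]), b$persistence)
})

test_that("lucdi is the changed-area fraction, bounded and exact", {
  mk <- function(a, b) {
    list(comp = zone_change_components(
      categorical_map(matrix(a, 1), timestamp = 2000),
      categorical_map(matrix(b, 1), timestamp = 2013),
      matrix(1L, 1, length(a))))
  }
  ten <- rep(1L, 10)
  # changed fractions 0, 0.4, 1 give lucdi 0, 0.4, 1 exactly
  expect_equal(lucdi(mk(ten, ten)$comp, 2000, 2013)$lucdi, 0)
  forty <- c(rep(2L, 4), rep(1L, 6))
  zd <- lucdi(mk(ten, forty)$comp, 2000, 2013)
  expect_equal(zd$lucdi, 0.4)
  expect_equal(zd$lucdi_annual, 0.4 / 13)
  expect_equal(lucdi(mk(ten, ten + 1L)$comp, 2000, 2013)$lucdi, 1)
  expect_error(lucdi(mk(ten, forty)$comp, 2013, 2000), "t_2 > t_1")
})

test_that("lucdi depends only on the changed/unchanged partition", {
  pair <- rand_map_pair(40, 40, seed = 31)
  zones <- generate_zones(pair$m1, 5, seed = 2)
  zd1 <- zone_dynamics(pair$m1, pair$m2, zones)
  # relabel classes by a fixed permutation in both maps
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  relab <- function(m) { m$grid <- matrix(perm[m$grid], nrow(m$grid)); m }
  zd2 <- zone_dynamics(relab(pair$m1), relab(pair$m2), zones)
  expect_equal(zd1$lucdi, zd2$lucdi)
})

test_that("lucdi of a zone union is the area-weighted mean of its parts", {
  pair <- rand_map_pair(30, 30, seed = 12)
  zg <- matrix(1L, 30, 30); zg[, 16:30] <- 2L
  parts <- lucdi(zone_change_components(pair$m1, pair$m2, zg), 2000, 2013)
  whole <- lucdi(zone_change_components(pair$m1, pair$m2, matrix(1L, 30, 30)),
                 2000, 2013)
  w <- parts$valid_cells / sum(parts$valid_cells)
  expect_equal(whole$lucdi, sum(w * parts$lucdi), tolerance = 1e-12)
})

test_that("kernel surface is maximal at a lone point and symmetric for twins", {
  template <- categorical_map(matrix(1L, 21, 21), cellsize = 1)
  one <- kernel_surface(data.frame(x = 10.5, y = 10.5, w = 1),
                        bandwidth = 5, template = template)
  # the maximum lies in the cell containing the point (row 11, col 11)
  idx <- arrayInd(which.max(one$grid), dim(one$grid))
  expect_equal(as.vector(idx), c(11, 11))

  two <- kernel_surface(data.frame(x = c(3.5, 17.5), y = c(10.5, 10.5),
                                   w = c(1, 1)),
                        bandwidth = 3, template = template)
  expect_equal(two$grid[11, 4], two$grid[11, 18], tolerance = 1e-9)
  expect_error(kernel_surface(data.frame(x = 1, y = 1, w = 1), bandwidth = 0,
                              template = template), "bandwidth")
})

test_that("kernel surface equals the double-loop oracle and is linear in weights", {
  template <- categorical_map(matrix(1L, 15, 18), cellsize = 2, xll = 5, yll = -3)
  pts <- withr::with_seed(9, data.frame(x = runif(5, 5, 41),
                                        y = runif(5, -3, 27),
                                        w = runif(5)))
  for (kern in c("quartic", "gaussian")) {
    surf <- kernel_surface(pts, bandwidth = 8, template = template, kernel = kern)
    expect_equal(surf$grid, oracle_kernel(pts, 8, template, kern),
                 tolerance = 1e-9)
  }
  s1 <- kernel_surface(pts, bandwidth = 8, template = template)
  pts2 <- pts; pts2$w <- 2 * pts2$w
  s2 <- kernel_surface(pts2, bandwidth = 8, template = template)
  expect_equal(s2$grid, 2 * s1$grid, tolerance = 1e-12)
})

test_that("covariate screening reports rank correlations, not miracles", {
  pair <- rand_map_pair(40, 40, seed = 77)
  zones <- generate_zones(pair$m1, 12, seed = 5)
  zd <- zone_dynamics(pair$m1, pair$m2, zones)
  cov <- data.frame(zone_id = zd$zone_id,
                    same = zd$lucdi, anti = -zd$lucdi)
  rep <- covariate_report(zd, cov)
  expect_equal(rep$spearman_rho[rep$covariate == "same"], 1)
  expect_equal(rep$spearman_rho[rep$covariate == "anti"], -1)
  expect_error(covariate_report(zd[1:2, ], cov[1:2, ]), "fewer than 3")

  # an independent covariate over 100 zones stays near zero for most seeds
  hits <- 0L
  for (s in 1:20) {
    sim <- withr::with_seed(1000 + s, data.frame(
      zone_id = 1:100, lucdi = stats::runif(100)))
    noise <- withr::with_seed(2000 + s, data.frame(
      zone_id = 1:100, v = stats::rnorm(100)))
    r <- covariate_report(sim, noise)
    if (abs(r$spearman_rho) < 0.3) hits <- hits + 1L
  }
  expect_gte(hits, 17L)
})
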