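test_that("ESRI ASCII grids round-trip bit-exactly including legend, nodata and transform", {
  withr::local_seed(42)
  g <- matrix(sample.int(6, 2500, TRUE), 50, 50)
  g[sample(2500, 30)] <- NA
  m <- categorical_map(g, cellsize = 30, xll = 1000.5, yll = -250.25,
                       legend = stats::setNames(six_classes, 1:6),
                       timestamp = 1992)
  path <- withr::local_tempfile(fileext = ".asc")
  write_categorical_map(m, path)
  back <- read_categorical_map(path, timestamp = 1992,
                               legend = paste0(path, ".legend.csv"))
  got <- back$grid
  got[!valid_cells(back)] <- NA
  expect_identical(got, m$grid)
  expect_identical(c(back$xll, back$yll, back$cellsize),
                   c(m$xll, m$yll, m$cellsize))
  expect_identical(back$legend, m$legend)
})

test_that("reading a constant single-code grid yields one class everywhere", {
  path <- write_temp_asc(c("ncols 3", "nrows 3", "xllcorner 0",
                           "yllcorner 0", "cellsize 1",
                           "1 1 1", "1 1 1", "1 1 1"))
  m <- read_categorical_map(path)
  expect_equal(dim(m$grid), c(3L, 3L))
  expect_true(all(m$grid == 1L))
  expect_equal(unname(m$legend["1"]), "class_1")
})

test_that("codes outside a strict legend and non-integer bands are refused", {
  path <- write_temp_asc(c("ncols 2", "nrows 1", "xllcorner 0",
                           "yllcorner 0", "cellsize 1", "1 7"))
  expect_error(
    read_categorical_map(path, legend = stats::setNames(six_classes, 1:6)),
    "absent from the legend")
  expect_silent(m <- read_categorical_map(
    path, legend = stats::setNames(six_classes, 1:6), strict = FALSE))
  expect_equal(unname(m$legend["7"]), "class_7")

  bad <- write_temp_asc(c("ncols 2", "nrows 1", "xllcorner 0",
                          "yllcorner 0", "cellsize 1", "1 1.5"))
  expect_error(read_categorical_map(bad), "non-integer")
  expect_error(read_categorical_map(tempfile(fileext = ".tif")), "not found")
})

test_that("alignment report flags shape, transform and crs differences", {
  m <- categorical_map(matrix(1L, 4, 4), cellsize = 1)
  expect_true(check_alignment(m, m)$ok)

  m2 <- categorical_map(matrix(1L, 4, 4), cellsize = 2)
  rep2 <- check_alignment(m, m2)
  expect_false(rep2$ok)
  expect_false(rep2$same_transform)
  expect_true(rep2$same_shape)

  # permuted legends over equal geometry: aligned, union of both legends
  a <- categorical_map(matrix(c(1L, 2L), 2, 2), legend = c("1" = "x", "2" = "y"))
  b <- categorical_map(matrix(c(2L, 3L), 2, 2), legend = c("2" = "y", "3" = "z"))
  rep3 <- check_alignment(a, b)
  expect_true(rep3$ok)
  expect_identical(rep3$legend_union, c("1" = "x", "2" = "y", "3" = "z"))
  # same code, different names: refuse rather than guess
  d <- categorical_map(matrix(2L, 2, 2), legend = c("2" = "other"))
  expect_error(check_alignment(a, d), "legends disagree")
})

test_that("polygon rasterization matches direct containment and partitions correctly", {
  template <- categorical_map(matrix(1L, 4, 4), cellsize = 1)
  whole <- zone_set(1L, polygons = list("1" = cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))))
  zg <- rasterize_zones(whole, template)
  expect_true(all(zg == 1L))

  halves <- zone_set(1:2, polygons = list(
    "1" = cbind(c(0, 2, 2, 0), c(0, 0, 4, 4)),
    "2" = cbind(c(2, 4, 4, 2), c(0, 0, 4, 4))))
  zg <- rasterize_zones(halves, template)
  expect_equal(as.vector(table(zg)), c(8L, 8L))

  # 3 random non-overlapping boxes on 100x100 vs direct box containment
  template <- categorical_map(matrix(1L, 100, 100), cellsize = 1)
  boxes <- list(c(3, 10, 5, 40), c(15, 60, 50, 90), c(70, 95, 2, 30)) # x0,x1,y0,y1
  polys <- lapply(boxes, function(b)
    cbind(c(b[1], b[2], b[2], b[1]), c(b[3], b[3], b[4], b[4])))
  names(polys) <- 1:3
  zs <- zone_set(1:3, polygons = polys)
  zg <- rasterize_zones(zs, template)
  cc <- cell_centers(template)
  for (k in 1:3) {
    b <- boxes[[k]]
    n_oracle <- sum(outer(cc$y > b[3] & cc$y < b[4], cc$x > b[1] & cc$x < b[2], "&"))
    expect_equal(sum(zg == k), n_oracle)
  }
  expect_lte(sum(zg != 0), length(zg))

  # a zone entirely outside the extent is kept, flagged, with zero cells
  far <- zone_set(1:2, polygons = list(
    "1" = cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)),
    "2" = cbind(c(500, 510, 510, 500), c(500, 500, 510, 510))))
  template <- categorical_map(matrix(1L, 4, 4), cellsize = 1)
  expect_warning(zg <- rasterize_zones(far, template), "covers no cell")
  expect_equal(sum(zg == 2L), 0L)
  # overlap is refused
  lap <- zone_set(1:2, polygons = list(
    "1" = cbind(c(0, 3, 3, 0), c(0, 0, 4, 4)),
    "2" = cbind(c(2, 4, 4, 2), c(0, 0, 4, 4))))
  expect_error(rasterize_zones(lap, template), "overlap")
})

test_that("raster zones cover every valid cell wall-to-wall", {
  template <- categorical_map(matrix(sample.int(3, 100, TRUE), 10, 10))
  zmap <- categorical_map(matrix(rep(1:2, each = 50), 10, 10),
                          legend = c("1" = "north", "2" = "south"))
  zs <- zones_from_raster(zmap)
  zg <- rasterize_zones(zs, template)
  expect_equal(sum(zg != 0L), 100L)
  expect_equal(zs$name, c("north", "south"))
})

test_that("GeoJSON polygon zones read with ids, names and centroids", {
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(zone_id = 7, name = "west"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(list(0, 0), list(2, 0),
                                                   list(2, 2), list(0, 2),
                                                   list(0, 0))))))),
    auto_unbox = TRUE), path)
  zs <- read_zones_geojson(path)
  expect_equal(zs$zone_id, 7L)
  expect_equal(zs$name, "west")
  ce <- zone_centroids(zs)
  expect_equal(c(ce$x, ce$y), c(1, 1))
})
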