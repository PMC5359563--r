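#' Zone sets: spatial aggregation units for zonal dynamics
#'
#' A `zone_set` holds the "villages" over which the change dynamic index is
#' aggregated. Zones come either as polygons (GeoJSON) or as a zone-coded
#' raster; both are rasterized onto the analysis grid before use. Zone ids
#' must be unique positive integers and zones may not overlap.
#'
#' @param zone_id integer vector of unique positive zone ids.
#' @param name character vector of zone names (defaults to
#'   `"zone_<id>"`).
#' @param polygons optional named list (by zone id) of two-column
#'   `x`,`y` vertex matrices (outer ring, unclosed or closed).
#' @param grid optional integer matrix of per-cell zone ids (0 = no
#'   zone) aligned to `template`.
#' @param template `categorical_map` supplying the georeference of
#'   `grid` (required when `grid` is given).
#' @return an object of class `zone_set`.
#' @export
zone_set <- function(zone_id, name = NULL, polygons = NULL, grid = NULL,
                     template = NULL) {
  zone_id <- as.integer(zone_id)
  if (anyDuplicated(zone_id)) stop("zone ids must be unique")
  if (any(zone_id <= 0L)) stop("zone ids must be positive integers (0 is reserved for 'no zone')")
  if (is.null(name)) name <- paste0("zone_", zone_id)
  if (length(name) != length(zone_id)) stop("one name per zone id required")
  if (is.null(polygons) && is.null(grid))
    stop("a zone_set needs polygons or a zone-id grid")
  transform <- NULL
  if (!is.null(grid)) {
    if (is.null(template)) stop("a zone grid needs a template map for its georeference")
    storage.mode(grid) <- "integer"
    extra <- setdiff(unique(grid[grid != 0L & !is.na(grid)]), zone_id)
    if (length(extra)) stop("zone grid contains ids not in zone_id: ",
                            paste(extra, collapse = ", "))
    transform <- list(xll = template$xll, yll = template$yll,
                      cellsize = template$cellsize)
  }
  if (!is.null(polygons)) {
    if (is.null(names(polygons))) names(polygons) <- as.character(zone_id)
    if (!setequal(names(polygons), as.character(zone_id)))
      stop("polygons must be named by zone id")
  }
  structure(list(zone_id = zone_id, name = name, polygons = polygons,
                 grid = grid, transform = transform),
            class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zones (%s)\n", length(x$zone_id),
              if (is.null(x$polygons)) "raster" else "polygon"))
  invisible(x)
}

#' Build a zone set from a zone-coded raster
#'
#' Every distinct non-nodata code in the map becomes one zone.
#'
#' @param zone_map a [categorical_map] whose codes are zone ids.
#' @return a [zone_set].
#' @export
zones_from_raster <- function(zone_map) {
  g <- zone_map$grid
  if (!is.na(zone_map$nodata)) g[g == zone_map$nodata] <- 0L
  g[is.na(g)] <- 0L
  ids <- sort(unique(g[g != 0L]))
  if (!length(ids)) stop("zone raster contains no zones")
  nm <- zone_map$legend[as.character(ids)]
  nm[is.na(nm)] <- paste0("zone_", ids[is.na(nm)])
  zone_set(ids, name = unname(nm), grid = g, template = zone_map)
}

#' Read zones from a GeoJSON FeatureCollection of polygons
#'
#' Each feature must be a `Polygon` (outer ring used; holes are not
#' supported) with `zone_id` and optionally `name` in its properties.
#'
#' @param path GeoJSON file path.
#' @return a [zone_set].
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("expected a GeoJSON FeatureCollection: ", path)
  ids <- integer(0); nms <- character(0); polys <- list()
  for (f in gj$features) {
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon"))
      stop("every feature must be a Polygon (got ",
           if (is.null(geom)) "NULL" else geom$type, ")")
    props <- f$properties
    if (is.null(props$zone_id)) stop("feature without a zone_id property")
    id <- as.integer(props$zone_id)
    ring <- geom$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(as.numeric(p[[1]]),
                                                    as.numeric(p[[2]]))))
    ids <- c(ids, id)
    nms <- c(nms, if (!is.null(props$name)) as.character(props$name)
                  else paste0("zone_", id))
    polys[[as.character(id)]] <- xy
  }
  zone_set(ids, name = nms, polygons = polys)
}

# Even-odd (ray casting) point-in-polygon, vectorized over points.
# Points exactly on an edge may fall either side; cell centres of a regular
# grid generically avoid polygon edges.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1L }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a zone set onto a template grid
#'
#' Cells are assigned by their centre point; cells outside every zone get
#' the reserved id 0. Overlapping polygons are an error (zones must
#' partition, not stack); a zone that covers no cell is kept with a
#' warning.
#'
#' @param zones a [zone_set].
#' @param template a [categorical_map] defining the target grid.
#' @return integer matrix of zone ids (0 = no zone) with the template's
#'   dimensions.
#' @export
rasterize_zones <- function(zones, template) {
  if (!is.null(zones$grid)) {
    if (!identical(dim(zones$grid), dim(template$grid)))
      stop("zone grid dimensions do not match the template")
    tr <- zones$transform
    if (!isTRUE(all.equal(c(tr$xll, tr$yll, tr$cellsize),
                          c(template$xll, template$yll, template$cellsize),
                          tolerance = 1e-9)))
      stop("zone grid georeference does not match the template")
    return(zones$grid)
  }
  cc <- cell_centers(template)
  nr <- nrow(template$grid); nc <- ncol(template$grid)
  px <- rep(cc$x, each = nr)          # column-major order
  py <- rep(cc$y, times = nc)
  out <- matrix(0L, nr, nc)
  for (k in seq_along(zones$zone_id)) {
    id <- zones$zone_id[k]
    hit <- point_in_polygon(px, py, zones$polygons[[as.character(id)]])
    if (!any(hit)) {
      warning("zone ", id, " covers no cell of the template; retained with zero cells")
      next
    }
    clash <- hit & (out != 0L)
    if (any(clash))
      stop("zones overlap on the template grid (zone ", id, " and zone ",
           out[which(clash)[1]], ")")
    out[hit] <- id
  }
  out
}

#' Representative points (geometric centres) of zones
#'
#' Polygon zones use the polygon centroid (shoelace formula; the vertex
#' mean for degenerate zero-area rings). Raster zones use the mean of
#' their cell-centre coordinates. Non-convex zones may have a centre
#' outside themselves; it is still used, matching the geometric-centre
#' convention.
#'
#' @param zones a [zone_set].
#' @param template template map, required for raster zones.
#' @return data.frame with `zone_id`, `name`, `x`, `y`.
#' @export
zone_centroids <- function(zones, template = NULL) {
  n <- length(zones$zone_id)
  x <- numeric(n); y <- numeric(n)
  if (!is.null(zones$polygons)) {
    for (k in seq_len(n)) {
      ce <- polygon_centroid(zones$polygons[[as.character(zones$zone_id[k])]])
      x[k] <- ce[1]; y[k] <- ce[2]
    }
  } else {
    if (is.null(template))
      template <- list(grid = zones$grid, xll = zones$transform$xll,
                       yll = zones$transform$yll,
                       cellsize = zones$transform$cellsize)
    cc <- cell_centers(template)
    nr <- nrow(zones$grid)
    for (k in seq_len(n)) {
      idx <- which(zones$grid == zones$zone_id[k])
      if (!length(idx)) { x[k] <- NA_real_; y[k] <- NA_real_; next }
      rows <- (idx - 1L) %% nr + 1L
      cols <- (idx - 1L) %/% nr + 1L
      x[k] <- mean(cc$x[cols]); y[k] <- mean(cc$y[rows])
    }
  }
  data.frame(zone_id = zones$zone_id, name = zones$name, x = x, y = y,
             stringsAsFactors = FALSE)
}

polygon_centroid <- function(poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cross) / (6 * a), sum((y + yn) * cross) / (6 * a))
}
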