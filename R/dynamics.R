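#' Per-zone change components
#'
#' For every zone and class i over the jointly valid cells:
#' `nochange` is the area persisting as i, `increase` the area entering i
#' (j to i, j != i) and `decrease` the area leaving i (i to j, j != i).
#' Areas are reported in cells; multiply by `attr(, "cell_area")` for map
#' units.
#'
#' @param map_1,map_2 aligned [categorical_map] objects.
#' @param zones a [zone_set] (rasterized onto the map grid) or an integer
#'   zone-id matrix already aligned to it.
#' @return long data.frame `zone_id`, `class`, `nochange`, `increase`,
#'   `decrease` (cells), with attributes `cell_area`, `classes` and
#'   `empty_zones` (ids of zones with no valid cell, all-zero rows kept).
#' @export
zone_change_components <- function(map_1, map_2, zones) {
  al <- check_alignment(map_1, map_2)
  if (!al$ok) stop("maps are not aligned; refusing zonal components")
  if (inherits(zones, "zone_set")) {
    zgrid <- rasterize_zones(zones, map_1)
    zone_ids <- zones$zone_id
  } else {
    zgrid <- zones
    if (!identical(dim(zgrid), dim(map_1$grid)))
      stop("zone grid dimensions do not match the maps")
    zone_ids <- sort(unique(zgrid[zgrid != 0L]))
  }
  legend <- al$legend_union
  codes <- as.integer(names(legend))
  classes <- unname(legend)
  ok <- valid_cells(map_1) & valid_cells(map_2) & zgrid != 0L
  a <- map_1$grid[ok]; b <- map_2$grid[ok]; z <- zgrid[ok]
  zf <- factor(z, levels = zone_ids)
  K <- length(codes)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    code <- codes[k]
    nochange <- as.numeric(table(zf[a == code & b == code]))
    increase <- as.numeric(table(zf[b == code & a != code]))
    decrease <- as.numeric(table(zf[a == code & b != code]))
    out[[k]] <- data.frame(zone_id = zone_ids, class = classes[k],
                           nochange = nochange, increase = increase,
                           decrease = decrease, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$zone_id, zone_ids), match(res$class, classes)), ]
  rownames(res) <- NULL
  per_zone <- tapply(res$nochange + res$increase, res$zone_id, sum)
  empty <- as.integer(names(per_zone)[per_zone == 0])
  if (length(empty))
    warning("zone(s) with no valid cell: ", paste(empty, collapse = ", "),
            "; components reported as zero")
  attr(res, "cell_area") <- map_1$cellsize^2
  attr(res, "classes") <- classes
  attr(res, "empty_zones") <- empty
  res
}

#' Zone-level land-cover change dynamic index (LUCDI)
#'
#' A two-way change-intensity index per zone:
#' \deqn{LUCDI = \frac{\sum_i Increase_i + \sum_i Decrease_i}{2 \cdot A}}
#' where A is the zone's valid area. Because each changed cell is counted
#' once as an increase and once as a decrease, LUCDI is the changed-area
#' fraction of the zone: 0 iff nothing changed, 1 iff no cell persisted.
#' The annualized rate `lucdi_annual = lucdi / (t_2 - t_1)` is reported
#' separately so the index itself keeps its [0, 1] range.
#'
#' @param components output of [zone_change_components()].
#' @param t_1,t_2 decimal years bounding the period (`t_2 > t_1`).
#' @return data.frame `zone_id`, `valid_cells`, `changed_cells`, `lucdi`,
#'   `lucdi_annual`; zones without valid cells get `NA` indices.
#' @export
lucdi <- function(components, t_1, t_2) {
  if (!is.numeric(t_1) || !is.numeric(t_2) || is.na(t_1) || is.na(t_2) ||
      t_2 <= t_1)
    stop("need t_2 > t_1 to compute the dynamic index (got ", t_1, ", ", t_2, ")")
  inc <- tapply(components$increase, components$zone_id, sum)
  dec <- tapply(components$decrease, components$zone_id, sum)
  per <- tapply(components$nochange, components$zone_id, sum)
  zid <- as.integer(names(inc))
  area <- per + inc  # persistent + changed cells
  idx <- (inc + dec) / (2 * area)
  idx[area == 0] <- NA_real_
  out <- data.frame(zone_id = zid, valid_cells = as.numeric(area),
                    changed_cells = as.numeric(inc),
                    lucdi = as.numeric(idx),
                    lucdi_annual = as.numeric(idx) / (t_2 - t_1),
                    stringsAsFactors = FALSE)
  out[order(out$zone_id), ]
}

#' Full zonal dynamics: components + LUCDI + representative points
#'
#' Convenience wrapper running [zone_change_components()] and [lucdi()]
#' and attaching each zone's geometric centre, ready for
#' [kernel_surface()]. Timestamps are taken from the maps.
#'
#' @param map_1,map_2 aligned, timestamped [categorical_map] objects.
#' @param zones a [zone_set].
#' @return a `zone_dynamics` data.frame: `zone_id`, `name`,
#'   `valid_cells`, `changed_cells`, `lucdi`, `lucdi_annual`,
#'   `centroid_x`, `centroid_y`; the component table rides along as
#'   `attr(, "components")`.
#' @export
zone_dynamics <- function(map_1, map_2, zones) {
  comp <- zone_change_components(map_1, map_2, zones)
  zd <- lucdi(comp, map_1$timestamp, map_2$timestamp)
  ce <- zone_centroids(zones, template = map_1)
  out <- merge(ce, zd, by = "zone_id", sort = TRUE)
  names(out)[names(out) == "x"] <- "centroid_x"
  names(out)[names(out) == "y"] <- "centroid_y"
  out <- out[, c("zone_id", "name", "valid_cells", "changed_cells",
                 "lucdi", "lucdi_annual", "centroid_x", "centroid_y")]
  attr(out, "components") <- comp
  attr(out, "period") <- c(map_1$timestamp, map_2$timestamp)
  class(out) <- c("zone_dynamics", "data.frame")
  out
}

#' Kernel-smoothed intensity surface from weighted zone points
#'
#' Places a radially symmetric kernel of bandwidth `h` at every
#' representative point and sums the weighted contributions on the
#' template grid — the raster-GIS "kernel density" operation. The default
#' quartic (biweight) kernel
#' \deqn{K(u) = \frac{3}{\pi h^2}(1 - u^2)^2, \quad u = d/h < 1}
#' is the one that tool family uses; a Gaussian is available. The surface
#' is a relative intensity (unnormalized weighted KDE): doubling all
#' weights doubles it everywhere.
#'
#' @param points data.frame with `x`, `y` and a weight column `w` (a
#'   `zone_dynamics` object is accepted: its centroids and `lucdi` values
#'   are used).
#' @param bandwidth kernel radius in map units (> 0). Default: 1/10 of the
#'   template's longer side.
#' @param template [categorical_map] defining the output grid.
#' @param kernel `"quartic"` (default) or `"gaussian"`.
#' @return a `dynamics_surface`: numeric grid plus georeference,
#'   `bandwidth` and `kernel_name`.
#' @export
kernel_surface <- function(points, bandwidth = NULL, template,
                           kernel = c("quartic", "gaussian")) {
  kernel <- match.arg(kernel)
  if (inherits(points, "zone_dynamics"))
    points <- data.frame(x = points$centroid_x, y = points$centroid_y,
                         w = points$lucdi)
  if (!all(c("x", "y", "w") %in% names(points)))
    stop("points need columns x, y and w")
  pts <- points[is.finite(points$x) & is.finite(points$y) & is.finite(points$w), ]
  if (nrow(pts) < 1L) stop("need at least one point with finite coordinates and weight")
  if (is.null(bandwidth))
    bandwidth <- 0.1 * max(ncol(template$grid), nrow(template$grid)) *
      template$cellsize
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0")
  cc <- cell_centers(template)
  nr <- nrow(template$grid); nc <- ncol(template$grid)
  surf <- matrix(0, nr, nc)
  for (k in seq_len(nrow(pts))) {
    u2 <- outer((cc$y - pts$y[k])^2, (cc$x - pts$x[k])^2, "+") / bandwidth^2
    kv <- if (kernel == "quartic") {
      ifelse(u2 < 1, 3 / (pi * bandwidth^2) * (1 - u2)^2, 0)
    } else {
      exp(-u2 / 2) / (2 * pi * bandwidth^2)
    }
    surf <- surf + pts$w[k] * kv
  }
  if (all(pts$w == 0)) warning("all point weights are zero; surface is identically zero")
  structure(list(grid = surf, xll = template$xll, yll = template$yll,
                 cellsize = template$cellsize, crs = template$crs,
                 bandwidth = bandwidth, kernel_name = kernel),
            class = "dynamics_surface")
}

#' @export
print.dynamics_surface <- function(x, ...) {
  cat(sprintf("<dynamics_surface> %d x %d, %s kernel, bandwidth %g, max %.4g\n",
              nrow(x$grid), ncol(x$grid), x$kernel_name, x$bandwidth,
              max(x$grid)))
  invisible(x)
}

#' Write a dynamics surface as an ESRI ASCII grid
#' @param surface a `dynamics_surface`.
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  write_ascii_grid(surface$grid, path, surface$xll, surface$yll,
                   surface$cellsize, nodata = NA)
  invisible(path)
}

#' Rank correlation of zone dynamics with candidate drivers
#'
#' Purely descriptive screening: Spearman rank correlation of each
#' covariate with the zones' LUCDI values, plus the paired data for
#' scatter plots. No causal claim is made or implied.
#'
#' @param zone_dyn a `zone_dynamics` data.frame (or anything with
#'   `zone_id` and `lucdi`).
#' @param covariates data.frame keyed by `zone_id` with numeric covariate
#'   columns.
#' @return data.frame `covariate`, `n`, `spearman_rho`, `p_value`;
#'   matched pairs in `attr(, "pairs")`.
#' @export
covariate_report <- function(zone_dyn, covariates) {
  if (!"zone_id" %in% names(covariates))
    stop("covariates must be keyed by a zone_id column")
  m <- merge(as.data.frame(zone_dyn)[, c("zone_id", "lucdi")], covariates,
             by = "zone_id")
  m <- m[is.finite(m$lucdi), ]
  if (nrow(m) < 3L)
    stop("fewer than 3 zones match between dynamics and covariates; ",
         "cannot report correlations")
  vars <- setdiff(names(covariates), "zone_id")
  rows <- lapply(vars, function(v) {
    x <- m[[v]]
    keep <- is.finite(x)
    ct <- suppressWarnings(
      stats::cor.test(m$lucdi[keep], x[keep], method = "spearman"))
    data.frame(covariate = v, n = sum(keep),
               spearman_rho = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pairs") <- m
  out
}
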