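#' Categorical land-cover map
#'
#' The basic container consumed by every analysis stage: a grid of integer
#' class codes with a square-cell georeference (lower-left corner + cell
#' size, rows running north to south as in the ESRI ASCII grid convention),
#' a legend mapping codes to class names, an optional nodata code, and a
#' decimal-year timestamp.
#'
#' @param grid integer matrix of class codes; row 1 is the northernmost row.
#' @param cellsize cell edge length in map units (> 0).
#' @param xll,yll x/y coordinate of the lower-left corner of the grid.
#' @param crs opaque coordinate-reference identifier, compared as text.
#'   No reprojection is ever attempted; mismatches are refused downstream.
#' @param legend named character vector mapping codes (names) to class
#'   names (values), or `NULL` to auto-name present codes as
#'   `"class_<code>"`.
#' @param nodata integer code marking cells outside the study area, or
#'   `NA` if every cell is valid.
#' @param timestamp decimal year the map represents (`t1`/`t2` of the
#'   zonal dynamic index); may be `NA` for timeless grids such as zone ids.
#' @param strict if `TRUE` (default) a code present in the grid but absent
#'   from a supplied legend is an error; if `FALSE` missing codes are
#'   auto-named.
#'
#' @return an object of class `categorical_map`.
#' @export
categorical_map <- function(grid, cellsize = 1, xll = 0, yll = 0,
                            crs = NA_character_, legend = NULL,
                            nodata = NA_integer_, timestamp = NA_real_,
                            strict = TRUE) {
  if (!is.matrix(grid)) grid <- as.matrix(grid)
  if (nrow(grid) < 1L || ncol(grid) < 1L)
    stop("grid must have at least one row and one column")
  if (!is.numeric(grid))
    stop("grid must be numeric with integer class codes")
  if (any(is.finite(grid) & grid != round(grid)))
    stop("grid contains non-integer values; categorical maps need integer class codes")
  storage.mode(grid) <- "integer"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || !is.finite(cellsize) ||
      cellsize <= 0)
    stop("cellsize must be a single positive number")
  nodata <- if (length(nodata) && !is.na(nodata)) as.integer(nodata) else NA_integer_

  present <- sort(unique(grid[!is.na(grid)]))
  if (!is.na(nodata)) present <- setdiff(present, nodata)
  if (is.null(legend)) {
    legend <- stats::setNames(paste0("class_", present), as.character(present))
  } else {
    legend <- validate_legend(legend)
    missing <- setdiff(as.character(present), names(legend))
    if (length(missing)) {
      if (strict)
        stop("grid contains codes absent from the legend: ",
             paste(missing, collapse = ", "))
      legend <- c(legend, stats::setNames(paste0("class_", missing), missing))
      legend <- legend[order(as.integer(names(legend)))]
    }
  }

  structure(
    list(grid = grid, cellsize = as.numeric(cellsize),
         xll = as.numeric(xll), yll = as.numeric(yll),
         crs = as.character(crs), legend = legend, nodata = nodata,
         timestamp = as.numeric(timestamp)),
    class = "categorical_map")
}

validate_legend <- function(legend) {
  if (is.null(names(legend)) || any(names(legend) == ""))
    stop("legend must be a named vector: names are integer codes, values class names")
  codes <- suppressWarnings(as.integer(names(legend)))
  if (anyNA(codes)) stop("legend names must be integer codes")
  if (anyDuplicated(codes)) stop("legend codes must be unique")
  if (anyDuplicated(legend)) stop("legend class names must be unique")
  stats::setNames(as.character(legend), as.character(codes))[order(codes)]
}

#' @export
print.categorical_map <- function(x, ...) {
  cat(sprintf("<categorical_map> %d x %d cells, cellsize %g",
              nrow(x$grid), ncol(x$grid), x$cellsize))
  if (!is.na(x$timestamp)) cat(sprintf(", t = %g", x$timestamp))
  cat("\n")
  cat("  legend:", paste(names(x$legend), "=", x$legend, collapse = ", "), "\n")
  if (!is.na(x$nodata)) cat("  nodata:", x$nodata, "\n")
  invisible(x)
}

#' @export
dim.categorical_map <- function(x) dim(x$grid)

#' Logical mask of valid (non-nodata) cells
#' @param map a `categorical_map`.
#' @return logical matrix, `TRUE` where the cell carries a class code.
#' @export
valid_cells <- function(map) {
  ok <- !is.na(map$grid)
  if (!is.na(map$nodata)) ok <- ok & map$grid != map$nodata
  ok
}

#' Cell-centre coordinates of a map grid
#'
#' @param map a `categorical_map` (or anything carrying `grid`, `xll`,
#'   `yll`, `cellsize`).
#' @return list with `x` (length ncol, west to east) and `y` (length nrow,
#'   north to south, matching row order).
#' @export
cell_centers <- function(map) {
  nr <- nrow(map$grid); nc <- ncol(map$grid)
  list(x = map$xll + (seq_len(nc) - 0.5) * map$cellsize,
       y = map$yll + (nr - seq_len(nr) + 0.5) * map$cellsize)
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------

parse_ascii_header <- function(lines) {
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) != 2L || !grepl("^[A-Za-z_]+$", parts[1]) ||
        is.na(suppressWarnings(as.numeric(parts[2]))))
      break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  list(header = hdr, n = i)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 7L)
  h <- parse_ascii_header(lines)
  hdr <- h$header
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]])) stop("ASCII grid header is missing '", key, "': ", path)
  if (!is.null(hdr$xllcorner)) xll <- hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) xll <- hdr$xllcenter - hdr$cellsize / 2
  else stop("ASCII grid header is missing xllcorner/xllcenter: ", path)
  if (!is.null(hdr$yllcorner)) yll <- hdr$yllcorner
  else if (!is.null(hdr$yllcenter)) yll <- hdr$yllcenter - hdr$cellsize / 2
  else stop("ASCII grid header is missing yllcorner/yllcenter: ", path)
  vals <- scan(path, what = numeric(), skip = h$n, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nr * nc, ": ", path)
  grid <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  list(grid = grid, xll = xll, yll = yll, cellsize = hdr$cellsize,
       nodata = if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA)
}

write_ascii_grid <- function(grid, path, xll, yll, cellsize, nodata = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid)),
    paste("nrows", nrow(grid)),
    paste("xllcorner", format(xll, digits = 17)),
    paste("yllcorner", format(yll, digits = 17)),
    paste("cellsize", format(cellsize, digits = 17))), con)
  g <- grid
  if (!is.na(nodata)) {
    writeLines(paste("NODATA_value", nodata), con)
    g[is.na(g)] <- nodata
  }
  writeLines(apply(g, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = " ")), con)
  invisible(path)
}

#' Read a categorical map from an ESRI ASCII grid
#'
#' Single-band integer grids in the plain-text ESRI ASCII (`.asc`) format
#' are supported. GeoTIFF inputs must be converted first (e.g.
#' `gdal_translate -of AAIGrid in.tif out.asc`); categorical rasters must
#' never be resampled on the way in, so no on-the-fly conversion is done.
#'
#' @param path path to an `.asc` / `.grd` / `.txt` ESRI ASCII grid.
#' @param timestamp decimal year the map represents.
#' @param legend named character vector (code -> name), path to a
#'   two-column `code,name` CSV, or `NULL` for auto-naming.
#' @param crs coordinate-reference identifier to attach (text).
#' @param strict error (default) or auto-name codes missing from `legend`.
#' @return a [categorical_map].
#' @export
read_categorical_map <- function(path, timestamp = NA_real_, legend = NULL,
                                 crs = NA_character_, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    stop("GeoTIFF input is not supported; convert to an ESRI ASCII grid ",
         "(e.g. gdal_translate -of AAIGrid) and re-read")
  if (!ext %in% c("asc", "grd", "txt", "agr"))
    stop("unrecognised raster format '.", ext, "'; expected an ESRI ASCII grid")
  r <- read_ascii_grid(path)
  body <- r$grid
  valid <- if (is.na(r$nodata)) !is.na(body) else !is.na(body) & body != r$nodata
  if (any(body[valid] != round(body[valid])))
    stop("non-integer band values in ", path,
         ": categorical maps need integer class codes")
  if (is.character(legend) && length(legend) == 1L && file.exists(legend))
    legend <- read_legend_csv(legend)
  categorical_map(body, cellsize = r$cellsize, xll = r$xll, yll = r$yll,
                  crs = crs, legend = legend,
                  nodata = if (is.na(r$nodata)) NA_integer_ else as.integer(r$nodata),
                  timestamp = timestamp, strict = strict)
}

#' Write a categorical map as an ESRI ASCII grid
#'
#' Round-trips bit-exactly with [read_categorical_map()] for integer grids.
#' The legend is written alongside as `<path>.legend.csv` unless
#' `legend_path = NA`.
#'
#' @param map a [categorical_map].
#' @param path output `.asc` path.
#' @param legend_path output CSV path for the legend, `NULL` for the
#'   default sidecar name, `NA` to skip.
#' @return `path`, invisibly.
#' @export
write_categorical_map <- function(map, path, legend_path = NULL) {
  nodata <- if (is.na(map$nodata)) {
    if (anyNA(map$grid)) -9999L else NA
  } else map$nodata
  write_ascii_grid(map$grid, path, map$xll, map$yll, map$cellsize, nodata)
  if (is.null(legend_path)) legend_path <- paste0(path, ".legend.csv")
  if (!is.na(legend_path)) write_legend_csv(map$legend, legend_path)
  invisible(path)
}

#' Read / write a class legend CSV
#'
#' Two columns, `code` (integer) and `name`.
#'
#' @param path CSV path.
#' @return named character vector, names = codes.
#' @export
read_legend_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "name") %in% names(df)))
    stop("legend CSV needs columns 'code' and 'name': ", path)
  validate_legend(stats::setNames(as.character(df$name), as.character(df$code)))
}

#' @rdname read_legend_csv
#' @param legend named character vector (code -> name).
#' @export
write_legend_csv <- function(legend, path) {
  utils::write.csv(
    data.frame(code = as.integer(names(legend)), name = as.character(legend)),
    path, row.names = FALSE)
  invisible(path)
}

# ---- alignment --------------------------------------------------------------

#' Check that two maps are co-registered
#'
#' Cross-tabulation is only meaningful for cell-to-cell comparable grids;
#' downstream functions refuse pairs whose report is not `ok`. No
#' resampling is ever attempted: silently resampling categorical data
#' would fabricate transitions.
#'
#' @param map_a,map_b two [categorical_map] objects.
#' @return an `alignment_report`: flags `same_shape`, `same_transform`,
#'   `same_crs`, the merged `legend_union`, and `ok` (true iff all three
#'   flags are true).
#' @export
check_alignment <- function(map_a, map_b) {
  same_shape <- identical(dim(map_a$grid), dim(map_b$grid))
  same_transform <- isTRUE(all.equal(
    c(map_a$xll, map_a$yll, map_a$cellsize),
    c(map_b$xll, map_b$yll, map_b$cellsize),
    tolerance = 1e-9))
  same_crs <- (is.na(map_a$crs) && is.na(map_b$crs)) ||
    identical(map_a$crs, map_b$crs)
  structure(
    list(same_shape = same_shape, same_transform = same_transform,
         same_crs = same_crs,
         legend_union = merge_legends(map_a$legend, map_b$legend),
         ok = same_shape && same_transform && same_crs),
    class = "alignment_report")
}

merge_legends <- function(a, b) {
  clash <- intersect(names(a), names(b))
  bad <- clash[a[clash] != b[clash]]
  if (length(bad))
    stop("legends disagree on code(s) ", paste(bad, collapse = ", "))
  out <- c(a, b[setdiff(names(b), names(a))])
  out[order(as.integer(names(out)))]
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> ok: %s (shape %s, transform %s, crs %s)\n",
              x$ok, x$same_shape, x$same_transform, x$same_crs))
  invisible(x)
}
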