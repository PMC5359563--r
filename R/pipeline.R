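#' Run the full change analysis on a pair of maps
#'
#' Orchestrates ingest, alignment check, cross-tabulation, change budget,
#' transition signals, ranking and (when zones are given) zonal dynamics
#' with a kernel-smoothed surface, writing a machine-readable report
#' bundle to `out_dir`:
#' `transition_matrix.csv`, `change_budget.csv`, `signals.csv`,
#' `ranking.csv`, `zone_dynamics.csv`, `surface.asc`, and
#' `run_metadata.json` (inputs, parameters, residuals, package version).
#' Stage-tagged progress goes to stderr; reports never mix logs and data.
#'
#' @param config named list or path to a YAML/JSON config with fields:
#'   `map_1`, `map_2` (paths or `categorical_map` objects), `t_1`, `t_2`
#'   (decimal years), `out_dir`; optional `legend` (path or named
#'   vector), `zones` (GeoJSON path, zone-raster path, or `zone_set`),
#'   `class_order`, `threshold_d`, `threshold_r`, `rounding`
#'   (`"full"`/`"paper"`), `kernel`, `bandwidth`, `crs`.
#' @return invisibly, a list with the computed objects and output paths.
#' @export
run_change_analysis <- function(config) {
  cfg <- load_run_config(config)
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("[config] out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  maps <- stage("ingest", {
    lg <- cfg$legend
    m1 <- if (inherits(cfg$map_1, "categorical_map")) cfg$map_1
          else read_categorical_map(cfg$map_1, timestamp = cfg$t_1,
                                    legend = lg, crs = cfg$crs %||% NA_character_)
    m2 <- if (inherits(cfg$map_2, "categorical_map")) cfg$map_2
          else read_categorical_map(cfg$map_2, timestamp = cfg$t_2,
                                    legend = lg, crs = cfg$crs %||% NA_character_)
    if (!is.na(cfg$t_1 %||% NA)) m1$timestamp <- cfg$t_1
    if (!is.na(cfg$t_2 %||% NA)) m2$timestamp <- cfg$t_2
    if (!is.na(m1$timestamp) && !is.na(m2$timestamp) &&
        m2$timestamp <= m1$timestamp)
      stop("timestamps must be strictly increasing")
    list(m1 = m1, m2 = m2)
  })

  tm <- stage("crosstab", cross_tabulate(maps$m1, maps$m2,
                                         class_order = cfg$class_order))
  budget <- stage("budget", change_budget(tm))
  sig <- stage("signals", transition_signals(
    tm, threshold_d = cfg$threshold_d %||% 0.2,
    threshold_r = cfg$threshold_r %||% 0.5,
    rounding = cfg$rounding %||% "full"))
  rk <- stage("ranking", rank_signals(sig))

  paths <- list(
    transition_matrix = file.path(out_dir, "transition_matrix.csv"),
    change_budget = file.path(out_dir, "change_budget.csv"),
    signals = file.path(out_dir, "signals.csv"),
    ranking = file.path(out_dir, "ranking.csv"))
  write_transition_csv(tm, paths$transition_matrix)
  utils::write.csv(as.data.frame(budget), paths$change_budget, row.names = FALSE)
  write_signals_csv(sig, paths$signals)
  write_signals_csv(rk, paths$ranking)

  zd <- surface <- NULL
  if (!is.null(cfg$zones)) {
    zones <- stage("zones", {
      z <- cfg$zones
      if (inherits(z, "zone_set")) z
      else if (grepl("\\.(geojson|json)$", z, ignore.case = TRUE))
        read_zones_geojson(z)
      else zones_from_raster(read_categorical_map(z, strict = FALSE))
    })
    zd <- stage("dynamics", zone_dynamics(maps$m1, maps$m2, zones))
    surface <- stage("surface", kernel_surface(
      zd, bandwidth = cfg$bandwidth, template = maps$m1,
      kernel = cfg$kernel %||% "quartic"))
    paths$zone_dynamics <- file.path(out_dir, "zone_dynamics.csv")
    paths$surface <- file.path(out_dir, "surface.asc")
    utils::write.csv(as.data.frame(zd), paths$zone_dynamics, row.names = FALSE)
    write_surface(surface, paths$surface)
  }

  paths$run_metadata <- file.path(out_dir, "run_metadata.json")
  write_run_metadata(paths$run_metadata, cfg, tm, sig, surface)
  message("[done] reports written to ", out_dir)
  invisible(list(transition_matrix = tm, change_budget = budget,
                 signals = sig, ranking = rk, zone_dynamics = zd,
                 surface = surface, paths = paths))
}

#' Analyse a published transition matrix (table mode)
#'
#' The non-spatial half of the pipeline for users who only have a printed
#' percentage matrix: change budget, transition signals and ranking, with
#' the same report files (minus the spatial ones).
#'
#' @param matrix_csv path to a transition-matrix CSV (square, `class`
#'   first column; marginal `row_total`/`loss` columns and
#'   `col_total`/`gain` rows are honoured when present).
#' @param out_dir report directory.
#' @param period numeric `(t_1, t_2)` years.
#' @param threshold_d,threshold_r signal label thresholds (see
#'   [transition_signals()]).
#' @param rounding `"full"` or `"paper"`.
#' @return invisibly, a list with the computed objects and output paths.
#' @export
run_table_mode <- function(matrix_csv, out_dir,
                           period = c(NA_real_, NA_real_),
                           threshold_d = 0.2, threshold_r = 0.5,
                           rounding = "full") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tm <- read_transition_csv(matrix_csv, period = period)
  budget <- change_budget(tm)
  sig <- transition_signals(tm, threshold_d = threshold_d,
                            threshold_r = threshold_r, rounding = rounding)
  rk <- rank_signals(sig)
  paths <- list(
    transition_matrix = file.path(out_dir, "transition_matrix.csv"),
    change_budget = file.path(out_dir, "change_budget.csv"),
    signals = file.path(out_dir, "signals.csv"),
    ranking = file.path(out_dir, "ranking.csv"),
    run_metadata = file.path(out_dir, "run_metadata.json"))
  write_transition_csv(tm, paths$transition_matrix)
  utils::write.csv(as.data.frame(budget), paths$change_budget, row.names = FALSE)
  write_signals_csv(sig, paths$signals)
  write_signals_csv(rk, paths$ranking)
  cfg <- list(mode = "table", matrix_csv = matrix_csv, out_dir = out_dir,
              threshold_d = threshold_d, threshold_r = threshold_r,
              rounding = rounding)
  write_run_metadata(paths$run_metadata, cfg, tm, sig, NULL)
  invisible(list(transition_matrix = tm, change_budget = budget,
                 signals = sig, ranking = rk, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  if (!is.null(config$legend) && is.character(config$legend) &&
      length(config$legend) == 1L && file.exists(config$legend))
    config$legend <- read_legend_csv(config$legend)
  config
}

write_run_metadata <- function(path, cfg, tm, sig, surface) {
  meta <- list(
    package = "changescape",
    version = as.character(utils::packageVersion("changescape")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    period = tm$period,
    basis = tm$basis,
    source = tm$source,
    percent_sum_residual = tm$residual,
    area_convention = "percentages are relative to cells valid (non-nodata) at both dates",
    threshold_d = attr(sig, "threshold_d"),
    threshold_r = attr(sig, "threshold_r"),
    rounding = attr(sig, "rounding"),
    kernel = if (!is.null(surface)) surface$kernel_name else NULL,
    bandwidth = if (!is.null(surface)) surface$bandwidth else NULL,
    config = cfg[!vapply(cfg, function(x)
      is.environment(x) || inherits(x, "categorical_map") ||
        inherits(x, "zone_set"), logical(1))])
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
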