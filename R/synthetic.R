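#' Configuration for synthetic landscape pairs
#'
#' Bundles and validates everything the generator needs: grid size,
#' time-1 class shares, the per-pixel Markov transition matrix, optional
#' spatial clustering (majority-smoothing passes), the number of Voronoi
#' zones, a seed and the period. Defaults emulate the kind of six-class
#' hilly-landscape mosaics the analysis is aimed at: a landscape dominated
#' by cultivated and (immature) forest land evolving under the 2000-2013
#' published transition structure, with mild spatial clustering and a few
#' dozen village-sized zones.
#'
#' @param n_rows,n_cols grid dimensions (default 200 x 200).
#' @param class_shares non-negative time-1 shares summing to 1; default:
#'   the published 2000 composition of the six classes.
#' @param markov K x K row-stochastic per-pixel transition matrix;
#'   default: rows of the published 2000-2013 matrix normalized by their
#'   row totals ([markov_from_transition()]).
#' @param clustering non-negative integer majority-smoothing passes for
#'   the time-1 map (0 = i.i.d. cells; default 1).
#' @param change_clustering smoothing passes applied to changed cells of
#'   the time-2 map (default 0).
#' @param n_zones number of Voronoi zones (default 25).
#' @param seed integer RNG seed.
#' @param period numeric `(t_1, t_2)` years (default `c(2000, 2013)`).
#' @param classes class names (default the six land-cover codes FL, IFL,
#'   CL, O, CoL, W).
#' @param cellsize cell edge length in map units (default 30, a Landsat
#'   pixel).
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_rows = 200, n_cols = 200,
                             class_shares = NULL, markov = NULL,
                             clustering = 1L, change_clustering = 0L,
                             n_zones = 25L, seed = 1L,
                             period = c(2000, 2013), classes = NULL,
                             cellsize = 30) {
  if (is.null(class_shares) || is.null(markov) || is.null(classes)) {
    fix <- table1_fixture("2000-2013")
    if (is.null(classes)) classes <- fix$classes
    if (is.null(class_shares))
      class_shares <- unname(fix$row_totals) / sum(fix$row_totals)
    if (is.null(markov)) markov <- markov_from_transition(fix)
  }
  K <- length(class_shares)
  if (K < 2L) stop("need at least two classes")
  if (length(classes) != K) stop("one class name per share required")
  if (any(class_shares < 0)) stop("class shares must be non-negative")
  if (abs(sum(class_shares) - 1) > 1e-9)
    stop("class shares must sum to 1 (got ", sum(class_shares), ")")
  markov <- as.matrix(markov)
  if (!identical(dim(markov), c(K, K))) stop("markov must be K x K")
  if (any(markov < 0) || any(abs(rowSums(markov) - 1) > 1e-9))
    stop("markov rows must be non-negative and sum to 1")
  if (clustering < 0 || change_clustering < 0)
    stop("clustering passes must be non-negative")
  if (n_rows < 1 || n_cols < 1) stop("grid must be at least 1 x 1")
  if (period[2] <= period[1]) stop("period must be increasing")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 class_shares = as.numeric(class_shares), markov = markov,
                 clustering = as.integer(clustering),
                 change_clustering = as.integer(change_clustering),
                 n_zones = as.integer(n_zones), seed = as.integer(seed),
                 period = as.numeric(period), classes = as.character(classes),
                 cellsize = as.numeric(cellsize)),
            class = "synthetic_config")
}

# 3x3 neighbour count (including the cell itself) of a logical matrix,
# zero-padded at the edges.
neighbor_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  out
}

# Deterministic majority smoothing in a 3x3 neighbourhood; ties broken by
# the lowest class code so autocorrelated maps stay seed-reproducible.
majority_smooth <- function(grid, codes, passes) {
  for (p in seq_len(passes)) {
    best <- matrix(-1, nrow(grid), ncol(grid))
    winner <- grid
    for (code in codes) {             # ascending codes: first max wins ties
      cnt <- neighbor_count(grid == code)
      take <- cnt > best
      winner[take] <- code
      best[take] <- cnt[take]
    }
    grid <- winner
  }
  grid
}

#' Generate a synthetic time-1 landscape
#'
#' Cells are drawn i.i.d. from `class_shares`, then `clustering` passes of
#' deterministic 3x3 majority smoothing (ties to the lowest class code)
#' create spatial autocorrelation. Fully reproducible from the config
#' seed; smoothing shifts realized shares slightly, so share-recovery
#' checks apply to the unsmoothed (`clustering = 0`) generator.
#'
#' @param config a [synthetic_config].
#' @return a [categorical_map] with codes `1..K`, timestamped `t_1`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  K <- length(config$class_shares)
  grid <- withr::with_seed(config$seed, {
    v <- sample.int(K, config$n_rows * config$n_cols, replace = TRUE,
                    prob = config$class_shares)
    matrix(v, config$n_rows, config$n_cols)
  })
  if (config$clustering > 0L)
    grid <- majority_smooth(grid, seq_len(K), config$clustering)
  categorical_map(grid, cellsize = config$cellsize,
                  legend = stats::setNames(config$classes, seq_len(K)),
                  timestamp = config$period[1])
}

#' Evolve a landscape one period under a per-pixel Markov matrix
#'
#' Every cell's time-2 class is drawn from the markov row of its time-1
#' class, independently across cells, so the joint empirical transition
#' matrix converges to `share_i * markov_ij` as the grid grows. Optional
#' `change_clustering` passes re-assign *changed* cells to the 3x3
#' majority of the provisional time-2 map, spatially aggregating the
#' change (at the cost of exact per-row transition rates).
#'
#' @param map_1 time-1 [categorical_map] with codes `1..K`.
#' @param markov K x K row-stochastic matrix.
#' @param seed integer RNG seed.
#' @param change_clustering non-negative smoothing passes on changed cells.
#' @param timestamp decimal year for the returned map.
#' @return the time-2 [categorical_map].
#' @export
evolve_landscape <- function(map_1, markov, seed, change_clustering = 0L,
                             timestamp = NA_real_) {
  markov <- as.matrix(markov)
  K <- nrow(markov)
  if (any(markov < 0) || any(abs(rowSums(markov) - 1) > 1e-9))
    stop("markov rows must be non-negative and sum to 1")
  old <- map_1$grid
  new <- old
  ok <- valid_cells(map_1)
  withr::with_seed(seed, {
    for (i in seq_len(K)) {
      idx <- which(ok & old == i)
      if (length(idx))
        new[idx] <- sample.int(K, length(idx), replace = TRUE,
                               prob = markov[i, ])
    }
  })
  if (change_clustering > 0L) {
    smoothed <- majority_smooth(new, seq_len(K), change_clustering)
    changed <- ok & new != old
    new[changed] <- smoothed[changed]
  }
  categorical_map(new, cellsize = map_1$cellsize, xll = map_1$xll,
                  yll = map_1$yll, crs = map_1$crs, legend = map_1$legend,
                  nodata = map_1$nodata, timestamp = timestamp)
}

#' Per-pixel Markov matrix implied by a transition matrix
#'
#' Rows are `C_ij / C_i+`; classes with zero time-1 area get identity
#' rows. Rows are renormalized to sum exactly to 1 (published tables are
#' rounded).
#'
#' @param T a [transition_matrix].
#' @return K x K row-stochastic matrix.
#' @export
markov_from_transition <- function(T) {
  P <- T$P
  rs <- rowSums(P)
  M <- diag(nrow(P))
  nz <- rs > 0
  M[nz, ] <- P[nz, , drop = FALSE] / rs[nz]
  dimnames(M) <- dimnames(P)
  M
}

#' Published six-class transition-matrix fixtures
#'
#' The two 6x6 percentage transition matrices for the monitoring periods
#' 1992-2000 and 2000-2013 of a Loess Plateau county (classes: forest
#' land FL, immature forest land IFL, cultivated land CL, orchards O,
#' construction land CoL, water W), shipped as CSV resources with their
#' printed marginals and gain/loss columns.
#'
#' @param period `"1992-2000"` or `"2000-2013"`.
#' @return a published-basis [transition_matrix].
#' @export
table1_fixture <- function(period = c("1992-2000", "2000-2013")) {
  period <- match.arg(period)
  fname <- paste0("transition_", gsub("-", "_", period), ".csv")
  path <- system.file("extdata", fname, package = "changescape",
                      mustWork = TRUE)
  years <- as.numeric(strsplit(period, "-")[[1]])
  read_transition_csv(path, period = years)
}

#' Published transition-signal values (deviations and ratios)
#'
#' Long-format published D and R values (gain and loss sides) for the two
#' fixture periods, as printed at 2 decimals; used for regression checks
#' against [transition_signals()] on the [table1_fixture()] matrices.
#'
#' @inheritParams table1_fixture
#' @return data.frame `from`, `to`, `d_gain`, `r_gain`, `d_loss`, `r_loss`.
#' @export
published_signals_fixture <- function(period = c("1992-2000", "2000-2013")) {
  period <- match.arg(period)
  fname <- paste0("published_signals_", gsub("-", "_", period), ".csv")
  utils::read.csv(system.file("extdata", fname, package = "changescape",
                              mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Generate wall-to-wall Voronoi zones on a template grid
#'
#' `n_zones` seed cells are drawn uniformly without replacement; every
#' cell joins its nearest seed (cell-centre Euclidean distance, ties to
#' the lowest zone id). Deterministic per seed; every cell is assigned,
#' so zone areas partition the grid.
#'
#' @param template a [categorical_map].
#' @param n_zones number of zones (1..cell count).
#' @param seed integer RNG seed.
#' @return a raster-backed [zone_set] with ids `1..n_zones`.
#' @export
generate_zones <- function(template, n_zones, seed) {
  nr <- nrow(template$grid); nc <- ncol(template$grid)
  n <- nr * nc
  if (n_zones < 1L || n_zones > n) stop("n_zones must be in 1..", n)
  centers <- withr::with_seed(seed, sample.int(n, n_zones))
  cc <- cell_centers(template)
  crow <- (centers - 1L) %% nr + 1L
  ccol <- (centers - 1L) %/% nr + 1L
  cx <- cc$x[ccol]; cy <- cc$y[crow]
  px <- rep(cc$x, each = nr); py <- rep(cc$y, times = nc)
  d2 <- outer(px, cx, function(a, b) (a - b)^2) +
        outer(py, cy, function(a, b) (a - b)^2)
  assign <- max.col(-d2, ties.method = "first")
  zone_set(seq_len(n_zones), grid = matrix(assign, nr, nc),
           template = template)
}

#' Generate a full synthetic study: map pair plus zones
#'
#' One call producing everything the pipeline consumes, all reproducible
#' from the config seed (sub-seeds are derived deterministically).
#'
#' @param config a [synthetic_config].
#' @return list with `map_1`, `map_2`, `zones`, `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  map_1 <- generate_landscape(config)
  map_2 <- evolve_landscape(map_1, config$markov, seed = config$seed + 1L,
                            change_clustering = config$change_clustering,
                            timestamp = config$period[2])
  zones <- generate_zones(map_1, config$n_zones, seed = config$seed + 2L)
  list(map_1 = map_1, map_2 = map_2, zones = zones, config = config)
}
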