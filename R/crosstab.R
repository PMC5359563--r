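#' Transition (cross-tabulation) matrices
#'
#' A `transition_matrix` holds the joint class composition of a pair of
#' dates: entry (i, j) is the share of the study area that was class i at
#' time 1 and class j at time 2 ("percent" basis) or the corresponding
#' cell count ("cells" basis). The diagonal is persistence. Marginals are
#' the time-1 (row) and time-2 (column) compositions; per-class gross gain
#' is the column total minus persistence and gross loss the row total
#' minus persistence.
#'
#' Matrices re-keyed from rounded publications carry the *printed*
#' marginals and gain/loss columns when supplied — for published tables
#' those are the authoritative data, and re-summing rounded cells can
#' drift from them by a few hundredths.
#'
#' @name transition_matrix
NULL

new_transition_matrix <- function(P, classes, basis, period,
                                  row_totals = NULL, col_totals = NULL,
                                  gains = NULL, losses = NULL,
                                  source = "computed", residual = 0,
                                  counts = NULL) {
  dimnames(P) <- list(classes, classes)
  if (is.null(row_totals)) row_totals <- rowSums(P)
  if (is.null(col_totals)) col_totals <- colSums(P)
  if (is.null(gains))  gains  <- col_totals - diag(P)
  if (is.null(losses)) losses <- row_totals - diag(P)
  names(row_totals) <- names(col_totals) <- classes
  names(gains) <- names(losses) <- classes
  structure(list(classes = classes, P = P, basis = basis,
                 period = period, row_totals = row_totals,
                 col_totals = col_totals, gains = gains, losses = losses,
                 source = source, residual = residual, counts = counts),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<transition_matrix> %d classes, basis '%s'", length(x$classes),
              x$basis))
  if (!anyNA(x$period)) cat(sprintf(", period %g-%g", x$period[1], x$period[2]))
  cat(sprintf(" (%s)\n", x$source))
  print(round(x$P, digits))
  invisible(x)
}

#' Cross-tabulate two co-registered categorical maps
#'
#' Counts joint class occurrences over cells valid (non-nodata) at *both*
#' dates and, in percent basis, converts to percent of that jointly valid
#' area. Refuses misaligned map pairs.
#'
#' @param map_1,map_2 [categorical_map] objects at time 1 and time 2.
#' @param class_order optional character vector of class names fixing the
#'   matrix order; classes absent from both maps appear as zero
#'   rows/columns. Defaults to the legend union in code order.
#' @param basis `"percent"` (default) or `"cells"`.
#' @return a [transition_matrix]; percent-basis results keep the raw cell
#'   counts in `$counts`.
#' @export
cross_tabulate <- function(map_1, map_2, class_order = NULL,
                           basis = c("percent", "cells")) {
  basis <- match.arg(basis)
  al <- check_alignment(map_1, map_2)
  if (!al$ok)
    stop("maps are not aligned (shape ", al$same_shape, ", transform ",
         al$same_transform, ", crs ", al$same_crs, "); refusing to cross-tabulate")
  legend <- al$legend_union
  codes <- as.integer(names(legend))
  classes <- unname(legend)
  if (!is.null(class_order)) {
    if (!setequal(class_order, classes) && !all(class_order %in% classes))
      stop("class_order contains unknown classes: ",
           paste(setdiff(class_order, classes), collapse = ", "))
    ord <- match(class_order, classes)
    codes <- codes[ord]; classes <- classes[ord]
  }
  ok <- valid_cells(map_1) & valid_cells(map_2)
  if (!any(ok)) stop("no cell is valid at both dates; empty study area")
  tab <- table(factor(map_1$grid[ok], levels = codes),
               factor(map_2$grid[ok], levels = codes))
  counts <- matrix(as.numeric(tab), length(codes), length(codes),
                   dimnames = list(classes, classes))
  period <- c(map_1$timestamp, map_2$timestamp)
  if (basis == "cells")
    return(new_transition_matrix(counts, classes, "cells", period,
                                 counts = counts))
  new_transition_matrix(counts / sum(counts) * 100, classes, "percent",
                        period, counts = counts)
}

#' Build a transition matrix from a published percentage table
#'
#' For matrices re-keyed from print, rounding makes the cells sum to
#' slightly off 100; the residual is recorded and tolerated up to `tol`.
#' Printed marginals and gain/loss columns, when supplied, are stored as
#' the authoritative values (they are checked against the re-summed cells
#' within 0.05 per entry).
#'
#' @param P square non-negative matrix of percentages (row = time-1
#'   class, column = time-2 class).
#' @param classes character vector of class names.
#' @param period numeric `(t1, t2)` years.
#' @param row_totals,col_totals optional printed marginals.
#' @param gains,losses optional printed per-class gross gain / loss.
#' @param tol tolerated |sum(P) - 100| for rounded publications.
#' @return a [transition_matrix] with `source = "published"`.
#' @export
from_published_table <- function(P, classes, period,
                                 row_totals = NULL, col_totals = NULL,
                                 gains = NULL, losses = NULL, tol = 0.2) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("published table must be square")
  if (length(classes) != nrow(P)) stop("one class name per row required")
  if (any(P < 0)) stop("negative entry in published table")
  residual <- sum(P) - 100
  if (abs(residual) > tol)
    stop("published table sums to ", round(sum(P), 4),
         "; residual exceeds tolerance ", tol)
  chk <- function(given, computed, what) {
    if (is.null(given)) return(computed)
    if (length(given) != length(classes)) stop(what, " needs one value per class")
    if (any(abs(given - computed) > 0.1))
      warning("printed ", what, " differ from re-summed cells by more than 0.1 (",
              "max ", round(max(abs(given - computed)), 3),
              "); check the table transcription")
    given
  }
  dimnames(P) <- list(classes, classes)
  rt <- chk(row_totals, rowSums(P), "row totals")
  ct <- chk(col_totals, colSums(P), "column totals")
  g  <- chk(gains, ct - diag(P), "gains")
  l  <- chk(losses, rt - diag(P), "losses")
  new_transition_matrix(P, classes, "percent", as.numeric(period),
                        row_totals = rt, col_totals = ct,
                        gains = g, losses = l,
                        source = "published", residual = residual)
}

#' Convert a cell-basis matrix to percent basis
#'
#' @param T a cells-basis [transition_matrix].
#' @return the percent-basis equivalent.
#' @export
as_percent <- function(T) {
  if (T$basis == "percent") return(T)
  new_transition_matrix(T$P / sum(T$P) * 100, T$classes, "percent",
                        T$period, counts = T$counts)
}

#' Per-class change budget
#'
#' Decomposes the transition matrix into, per class j: persistence
#' \eqn{C_{jj}}, gross gain \eqn{Gain_j = C_{+j} - C_{jj}}, gross loss
#' \eqn{Loss_j = C_{j+} - C_{jj}}, net change \eqn{N_j = |Gain_j -
#' Loss_j|}, swap \eqn{S_j = 2\min(Gain_j, Loss_j)} (location-only
#' change), and total change \eqn{TC_j = Gain_j + Loss_j = N_j + S_j}.
#' Published matrices use their stored (printed) marginals and
#' gain/loss columns.
#'
#' @param T a [transition_matrix] (percent or cells basis).
#' @return a `change_budget` data.frame (class, persistence, gain, loss,
#'   net, swap, total) with attributes `overall_persistence` and
#'   `overall_change` (trace and its complement, percent basis only).
#' @export
change_budget <- function(T) {
  gain <- T$gains; loss <- T$losses
  out <- data.frame(class = T$classes,
                    persistence = unname(diag(T$P)),
                    gain = unname(gain), loss = unname(loss),
                    net = unname(abs(gain - loss)),
                    swap = unname(2 * pmin(gain, loss)),
                    total = unname(gain + loss),
                    stringsAsFactors = FALSE)
  attr(out, "basis") <- T$basis
  attr(out, "overall_persistence") <- sum(diag(T$P))
  attr(out, "overall_change") <-
    if (T$basis == "percent") 100 - sum(diag(T$P)) else sum(T$P) - sum(diag(T$P))
  class(out) <- c("change_budget", "data.frame")
  out
}

#' @export
print.change_budget <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  cat(sprintf("overall persistence %s, overall change %s\n",
              round(attr(x, "overall_persistence"), digits),
              round(attr(x, "overall_change"), digits)))
  invisible(x)
}

#' Export a transition matrix (or read one back) as CSV
#'
#' The layout is the printed-table convention: class names as the first
#' column and header; optional `row_total` and `loss` columns and
#' `col_total` / `gain` rows carry printed marginals. [read_transition_csv()]
#' understands both the plain square layout and the marginal-augmented one.
#'
#' @param T a [transition_matrix].
#' @param path CSV path.
#' @param marginals include marginal rows/columns (default `TRUE`).
#' @return `path` (write) or a [transition_matrix] (read).
#' @export
write_transition_csv <- function(T, path, marginals = TRUE) {
  df <- data.frame(class = T$classes, as.data.frame(T$P),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (marginals) {
    df$row_total <- unname(T$row_totals)
    df$loss <- unname(T$losses)
    extra <- data.frame(class = c("col_total", "gain"),
                        rbind(unname(T$col_totals), unname(T$gains)),
                        row_total = NA_real_, loss = NA_real_,
                        check.names = FALSE, stringsAsFactors = FALSE)
    names(extra) <- names(df)
    df <- rbind(df, extra)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_csv
#' @param period numeric `(t1, t2)` attached to the matrix read back.
#' @export
read_transition_csv <- function(path, period = c(NA_real_, NA_real_)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "class") stop("transition CSV must start with a 'class' column")
  marg_rows <- df$class %in% c("col_total", "gain")
  body <- df[!marg_rows, , drop = FALSE]
  classes <- body$class
  value_cols <- intersect(names(df), classes)
  if (length(value_cols) != length(classes))
    stop("transition CSV is not square: classes ", paste(classes, collapse = ","),
         " vs columns ", paste(setdiff(classes, value_cols), collapse = ","))
  P <- as.matrix(body[, classes])
  row_totals <- if ("row_total" %in% names(body)) body$row_total else NULL
  losses <- if ("loss" %in% names(body)) body$loss else NULL
  col_totals <- gains <- NULL
  if (any(marg_rows)) {
    m <- df[marg_rows, , drop = FALSE]
    if ("col_total" %in% m$class)
      col_totals <- as.numeric(m[m$class == "col_total", classes])
    if ("gain" %in% m$class)
      gains <- as.numeric(m[m$class == "gain", classes])
  }
  from_published_table(P, classes, period, row_totals = row_totals,
                       col_totals = col_totals, gains = gains, losses = losses)
}
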