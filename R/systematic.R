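#' Expected transitions under a random process of gain
#'
#' Under the null model that a class gains at random, class j's gross gain
#' is distributed across donor classes in proportion to their time-1
#' prevalence, excluding j itself:
#' \deqn{G_{ij} = Gain_j \cdot \frac{C_{i+}}{100 - C_{j+}}, \quad i \ne j}
#' Diagonal entries carry the observed persistence (persistence is held
#' fixed by the null model). A class occupying the whole map at time 1
#' has no donors; its column is returned as `NA` with a warning.
#'
#' @param T a percent-basis [transition_matrix].
#' @return K x K numeric matrix of expected gains.
#' @export
expected_gains <- function(T) {
  stopifnot(inherits(T, "transition_matrix"))
  if (T$basis != "percent")
    stop("expected gains are defined on a percent-basis matrix; see as_percent()")
  K <- length(T$classes)
  rt <- T$row_totals; gain <- T$gains
  G <- matrix(NA_real_, K, K, dimnames = list(T$classes, T$classes))
  for (j in seq_len(K)) {
    denom <- 100 - rt[j]
    if (denom <= 0) {
      warning("class '", T$classes[j], "' occupies the whole area at time 1; ",
              "expected gains for it are undefined")
      next
    }
    G[, j] <- gain[j] * rt / denom
  }
  diag(G) <- diag(T$P)
  G
}

#' Expected transitions under a random process of loss
#'
#' Mirror of [expected_gains()]: class i's gross loss is distributed
#' across recipient classes in proportion to their time-2 prevalence,
#' excluding i itself:
#' \deqn{L_{ij} = Loss_i \cdot \frac{C_{+j}}{100 - C_{+i}}, \quad i \ne j}
#'
#' @param T a percent-basis [transition_matrix].
#' @return K x K numeric matrix of expected losses.
#' @export
expected_losses <- function(T) {
  stopifnot(inherits(T, "transition_matrix"))
  if (T$basis != "percent")
    stop("expected losses are defined on a percent-basis matrix; see as_percent()")
  K <- length(T$classes)
  ct <- T$col_totals; loss <- T$losses
  L <- matrix(NA_real_, K, K, dimnames = list(T$classes, T$classes))
  for (i in seq_len(K)) {
    denom <- 100 - ct[i]
    if (denom <= 0) {
      warning("class '", T$classes[i], "' occupies the whole area at time 2; ",
              "expected losses for it are undefined")
      next
    }
    L[i, ] <- loss[i] * ct / denom
  }
  diag(L) <- diag(T$P)
  L
}

#' Systematic vs. random transition signals
#'
#' For every ordered off-diagonal class pair (i, j), compares the observed
#' transition share with its random-process expectation on the gain side
#' (\eqn{D = C_{ij} - G_{ij}}) and the loss side (\eqn{D = C_{ij} -
#' L_{ij}}), plus the prevalence-corrected ratio \eqn{R = D / expected}.
#' Deviations near zero indicate random inter-category transitions; large
#' positive D with large positive R marks a transition systematically
#' sought (`"systematic-to"`), large negative both marks one
#' systematically avoided (`"systematic-avoid"`), anything else is
#' `"random"`. A zero expectation leaves R undefined: the pair is
#' labelled `"random"` with `r_*_defined = FALSE`.
#'
#' `rounding = "paper"` rounds D and the expectation to 2 decimals before
#' taking the ratio, matching how ratios behave when recomputed from a
#' table printed at 2 decimals; the default keeps full precision.
#'
#' @param T a percent-basis [transition_matrix].
#' @param threshold_d minimum |D| (percentage points of study area) for a
#'   systematic label. Default 0.2 — small enough to keep transitions of
#'   minor classes whose ratio is large, the regime the ratio exists for.
#' @param threshold_r minimum |R| for a systematic label (default 0.5).
#' @param rounding `"full"` (default) or `"paper"`.
#' @return a `signal_table` data.frame in long format: `from`, `to`,
#'   `observed`, `expected_gain`, `d_gain`, `r_gain`, `r_gain_defined`,
#'   `label_gain`, and the same four columns for the loss side.
#' @export
transition_signals <- function(T, threshold_d = 0.2, threshold_r = 0.5,
                               rounding = c("full", "paper")) {
  rounding <- match.arg(rounding)
  G <- expected_gains(T)
  L <- expected_losses(T)
  K <- length(T$classes)
  ij <- which(row(G) != col(G))
  ord <- order(row(G)[ij], col(G)[ij])
  ij <- ij[ord]
  obs <- T$P[ij]
  side <- function(expected) {
    e <- expected[ij]
    d <- obs - e
    if (rounding == "paper") { d <- round(d, 2); e <- round(e, 2) }
    r <- ifelse(!is.na(e) & e > 0, d / e, NA_real_)
    label <- rep("random", length(d))
    label[!is.na(r) & d >  threshold_d & r >  threshold_r] <- "systematic-to"
    label[!is.na(r) & d < -threshold_d & r < -threshold_r] <- "systematic-avoid"
    list(e = e, d = d, r = r, defined = !is.na(r), label = label)
  }
  g <- side(G); l <- side(L)
  out <- data.frame(
    from = T$classes[row(G)[ij]], to = T$classes[col(G)[ij]],
    observed = obs,
    expected_gain = g$e, d_gain = g$d, r_gain = g$r,
    r_gain_defined = g$defined, label_gain = g$label,
    expected_loss = l$e, d_loss = l$d, r_loss = l$r,
    r_loss_defined = l$defined, label_loss = l$label,
    stringsAsFactors = FALSE)
  attr(out, "threshold_d") <- threshold_d
  attr(out, "threshold_r") <- threshold_r
  attr(out, "rounding") <- rounding
  attr(out, "classes") <- T$classes
  class(out) <- c("signal_table", "data.frame")
  out
}

#' Rank the dominant systematic transitions
#'
#' Keeps pairs labelled `"systematic-to"` on *both* the gain and the loss
#' side and orders them by descending `min(|d_gain|, |d_loss|)` — a
#' transition only ranks as high as its weaker evidence. Ties break
#' deterministically by (from, to) class order.
#'
#' @param S a `signal_table` from [transition_signals()].
#' @param k number of transitions to return; `NULL` (default) returns all.
#'   A `k` beyond the available pairs returns all of them, flagged via the
#'   `truncated` attribute and a warning.
#' @return data.frame `rank`, `from`, `to`, `score`, `d_gain`, `d_loss`,
#'   `r_gain`, `r_loss`.
#' @export
rank_signals <- function(S, k = NULL) {
  classes <- attr(S, "classes")
  sel <- S$label_gain == "systematic-to" & S$label_loss == "systematic-to"
  out <- S[sel, c("from", "to", "d_gain", "d_loss", "r_gain", "r_loss")]
  out$score <- pmin(abs(out$d_gain), abs(out$d_loss))
  ord <- order(-out$score, match(out$from, classes), match(out$to, classes))
  out <- out[ord, c("from", "to", "score", "d_gain", "d_loss", "r_gain", "r_loss")]
  truncated <- FALSE
  if (!is.null(k)) {
    if (k > nrow(out)) {
      if (nrow(out) > 0 || k > 0)
        warning("asked for top ", k, " but only ", nrow(out),
                " transitions are systematic on both sides; returning all")
      truncated <- TRUE
    } else out <- out[seq_len(k), , drop = FALSE]
  }
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  out
}

#' Export a signal table or ranking as CSV
#' @param S a `signal_table` or ranking data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_signals_csv <- function(S, path) {
  utils::write.csv(as.data.frame(S), path, row.names = FALSE)
  invisible(path)
}
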