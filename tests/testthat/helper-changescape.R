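# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (per-cell loops, direct sums) and share no
# code with the implementation paths they check.

six_classes <- c("FL", "IFL", "CL", "O", "CoL", "W")

# random percent-basis transition matrix summing exactly to 100
rand_percent_matrix <- function(K = 6, seed = 1) {
  withr::with_seed(seed, {
    P <- matrix(stats::runif(K * K), K, K)
    P <- P / sum(P) * 100
    from_published_table(P, paste0("c", seq_len(K)), c(2000, 2010), tol = 1e-6)
  })
}

rand_map_pair <- function(nr, nc, K = 6, seed = 1, cellsize = 1) {
  withr::with_seed(seed, {
    a <- matrix(sample.int(K, nr * nc, TRUE), nr, nc)
    b <- matrix(sample.int(K, nr * nc, TRUE), nr, nc)
    list(m1 = categorical_map(a, cellsize = cellsize, timestamp = 2000),
         m2 = categorical_map(b, cellsize = cellsize, timestamp = 2013))
  })
}

# per-cell loop oracle for the joint count matrix
oracle_crosstab_counts <- function(m1, m2, codes) {
  K <- length(codes)
  out <- matrix(0, K, K)
  g1 <- m1$grid; g2 <- m2$grid
  for (r in seq_len(nrow(g1))) for (c in seq_len(ncol(g1))) {
    a <- g1[r, c]; b <- g2[r, c]
    if (is.na(a) || is.na(b)) next
    if (!is.na(m1$nodata) && a == m1$nodata) next
    if (!is.na(m2$nodata) && b == m2$nodata) next
    i <- match(a, codes); j <- match(b, codes)
    out[i, j] <- out[i, j] + 1
  }
  out
}

# per-cell loop oracle for zone change components (cells)
oracle_zone_components <- function(m1, m2, zgrid, codes, zone_ids) {
  K <- length(codes)
  inc <- dec <- noc <- matrix(0, length(zone_ids), K,
                              dimnames = list(zone_ids, codes))
  g1 <- m1$grid; g2 <- m2$grid
  for (r in seq_len(nrow(g1))) for (c in seq_len(ncol(g1))) {
    z <- zgrid[r, c]
    if (z == 0) next
    a <- g1[r, c]; b <- g2[r, c]
    if (is.na(a) || is.na(b)) next
    if (!is.na(m1$nodata) && a == m1$nodata) next
    if (!is.na(m2$nodata) && b == m2$nodata) next
    zi <- match(z, zone_ids)
    if (a == b) noc[zi, match(a, codes)] <- noc[zi, match(a, codes)] + 1
    else {
      dec[zi, match(a, codes)] <- dec[zi, match(a, codes)] + 1
      inc[zi, match(b, codes)] <- inc[zi, match(b, codes)] + 1
    }
  }
  list(increase = inc, decrease = dec, nochange = noc)
}

# direct double-loop kernel-sum oracle
oracle_kernel <- function(pts, h, template, kernel = "quartic") {
  cc <- cell_centers(template)
  nr <- nrow(template$grid); nc <- ncol(template$grid)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    s <- 0
    for (k in seq_len(nrow(pts))) {
      d <- sqrt((cc$x[c] - pts$x[k])^2 + (cc$y[r] - pts$y[k])^2)
      u <- d / h
      kv <- if (kernel == "quartic") {
        if (u < 1) 3 / (pi * h^2) * (1 - u^2)^2 else 0
      } else exp(-u^2 / 2) / (2 * pi * h^2)
      s <- s + pts$w[k] * kv
    }
    out[r, c] <- s
  }
  out
}

# long signal table -> named lookup of one column
sig_value <- function(S, from, to, col) {
  S[S$from == from & S$to == to, col]
}

write_temp_asc <- function(lines) {
  path <- withr::local_tempfile(fileext = ".asc",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
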