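# Independent oracles used to validate the package's computational paths.
# These deliberately avoid the package's separable-convolution machinery:
# the local-moment oracle builds the full voxel-by-voxel weight matrix from
# coordinate differences and normalises it explicitly per voxel.

# Gaussian-weighted local moments / LNCC by direct full-grid summation.
# Same kernel definition as the package (per-axis truncation at
# `truncate * sigma`, zero weight outside the grid, per-voxel weight
# normalisation), but computed as W %*% x with an explicit weight matrix.
bruteforce_moments <- function(a, b, sigma, truncate = 4) {
  d <- dim(a)
  h <- max(1L, as.integer(ceiling(truncate * sigma)))
  k1 <- function(delta) ifelse(abs(delta) <= h,
                               exp(-delta^2 / (2 * sigma^2)), 0)
  coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                  z = seq_len(d[3])))
  n <- nrow(coords)
  W <- k1(outer(coords[, 1], coords[, 1], `-`)) *
    k1(outer(coords[, 2], coords[, 2], `-`)) *
    k1(outer(coords[, 3], coords[, 3], `-`))
  wsum <- W %*% rep(1, n)
  av <- as.numeric(a); bv <- as.numeric(b)
  ma <- as.numeric(W %*% av) / wsum
  mb <- as.numeric(W %*% bv) / wsum
  va <- pmax(as.numeric(W %*% av^2) / wsum - ma^2, 0)
  vb <- pmax(as.numeric(W %*% bv^2) / wsum - mb^2, 0)
  cv <- as.numeric(W %*% (av * bv)) / wsum - ma * mb
  list(mean_a = array(ma, d), mean_b = array(mb, d),
       sd_a = array(sqrt(va), d), sd_b = array(sqrt(vb), d),
       cov = array(cv, d))
}

bruteforce_lncc <- function(a, b, sigma, truncate = 4) {
  m <- bruteforce_moments(a, b, sigma, truncate)
  den <- m$sd_a * m$sd_b
  out <- m$cov / den
  pmin(pmax(out, -1), 1)
}

# Otsu by direct exhaustive search over the same 256-bin histogram,
# maximising between-class variance with an explicit two-class loop.
bruteforce_otsu <- function(x, nbins = 256) {
  edges <- seq(min(x), max(x), length.out = nbins + 1)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), nbins)
  best <- -Inf
  best_thr <- NA_real_
  for (k in 1:(nbins - 1)) {
    lo <- x[bin <= k]; hi <- x[bin > k]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(x)
    bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bcv > best) {
      best <- bcv
      best_thr <- edges[k + 1]
    }
  }
  best_thr
}

# Rating-rule oracle: direct hand tally of the printed rule for one voxel's
# per-condition counts.
rating_oracle <- function(counts, T) {
  thr <- ceiling(T / 2 + 1)
  mx <- max(counts)
  if (mx >= thr) which.max(counts) else 0L
}

# Naive pooled top-T + tally for a voxel-by-atlas value matrix (stable
# descending ties by column order), independent of the C++ kernel.
naive_top_counts <- function(V, cond_of_col, conditions, T) {
  t(apply(V, 1, function(row) {
    def <- which(!is.na(row))
    ord <- def[order(-row[def])]   # order() is stable
    top <- ord[seq_len(min(T, length(ord)))]
    vapply(conditions, function(cn) sum(cond_of_col[top] == cn), integer(1))
  }))
}

# Small helper: volume from array with unit spacing.
vol <- function(a) vx_volume(a, spacing = c(1, 1, 1))
msk <- function(a) vx_mask(a, spacing = c(1, 1, 1))
full_roi <- function(d) msk(array(TRUE, dim = d))
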