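# Local normalised cross-correlation (LNCC) and the moment machinery behind
# it. All local statistics are Gaussian-weighted: a local mean is the
# convolution of the image with a normalised Gaussian kernel, the local
# variance is E[I^2] - E[I]^2 under the same weighting, and the local
# covariance is E[IJ] - E[I]E[J]. Convolution uses zero padding with
# renormalisation by the convolved all-ones volume, so the weights at every
# voxel (boundary included) sum to one over the part of the kernel that lies
# inside the grid.

# Truncated, normalised 1D Gaussian kernel. Truncation at 4 sigma keeps the
# discarded mass below 1e-4 relative.
#' @keywords internal
gauss_kernel_1d <- function(sigma, truncate = 4) {
  stopifnot(sigma > 0)
  h <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Banded convolution matrix for one axis (zero padding implicit: entries
# falling outside [1, n] are dropped).
#' @keywords internal
conv_band_matrix <- function(n, kernel) {
  h <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in -h:h) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[off + h + 1L]
  }
  K
}

# Separable 3D Gaussian convolution (zero-padded, no renormalisation).
# Implemented as three banded-matrix multiplications so BLAS does the work.
#' @keywords internal
smooth3d_raw <- function(a, sigma, truncate = 4) {
  d <- dim(a)
  k <- gauss_kernel_1d(sigma, truncate)
  for (ax in 1:3) {
    K <- conv_band_matrix(d[ax], k)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    b <- K %*% matrix(b, nrow = db[1])
    dim(b) <- db
    a <- aperm(b, order(perm))
  }
  a
}

#' Gaussian smoothing of a 3D array with edge renormalisation
#'
#' Zero-padded separable Gaussian convolution divided by the convolution of an
#' all-ones array, so local averages are unbiased up to the grid boundary.
#'
#' @param a 3D numeric array.
#' @param sigma Gaussian standard deviation in voxels.
#' @param truncate kernel truncation radius in units of `sigma`.
#' @return Array of the same dimensions.
#' @export
gauss_smooth <- function(a, sigma, truncate = 4) {
  stopifnot(is.array(a), length(dim(a)) == 3L, sigma > 0)
  smooth3d_raw(a, sigma, truncate) / conv_norm(dim(a), sigma, truncate)
}

# Convolved all-ones volume: the per-voxel sum of in-grid kernel weights.
# Separable, so it is an outer product of three 1D profiles.
#' @keywords internal
conv_norm <- function(d, sigma, truncate = 4) {
  k <- gauss_kernel_1d(sigma, truncate)
  prof <- lapply(d, function(n) as.numeric(conv_band_matrix(n, k) %*% rep(1, n)))
  outer(outer(prof[[1]], prof[[2]]), prof[[3]]) |>
    array(dim = d)
}

#' Gaussian-weighted local moments of an image pair
#'
#' Computes, at every voxel, the Gaussian-weighted local means, standard
#' deviations and covariance of two volumes: `mean = G * I`,
#' `var = G * I^2 - (G * I)^2`, `cov = G * (I J) - (G * I)(G * J)`, with the
#' zero-pad + renormalise boundary rule. Variances are clamped at zero before
#' the square root.
#'
#' @param a,b [vx_volume]s on the same grid.
#' @param sigma_g Gaussian window standard deviation in voxels.
#' @return A list of class `vx_moments` with arrays `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `cov`.
#' @export
local_moments <- function(a, b, sigma_g) {
  stopifnot(is_vx_volume(a), is_vx_volume(b), sigma_g > 0)
  check_same_geometry(a, b, "moment inputs")
  d <- dim(a$data)
  nrm <- conv_norm(d, sigma_g)
  ma <- smooth3d_raw(a$data, sigma_g) / nrm
  mb <- smooth3d_raw(b$data, sigma_g) / nrm
  va <- pmax(smooth3d_raw(a$data^2, sigma_g) / nrm - ma^2, 0)
  vb <- pmax(smooth3d_raw(b$data^2, sigma_g) / nrm - mb^2, 0)
  cv <- smooth3d_raw(a$data * b$data, sigma_g) / nrm - ma * mb
  structure(list(mean_a = ma, mean_b = mb,
                 sd_a = sqrt(va), sd_b = sqrt(vb), cov = cv),
            class = "vx_moments")
}

#' Local normalised correlation coefficient map
#'
#' Per-voxel Pearson correlation of two volumes under a Gaussian spatial
#' weighting: `LNCC(x) = cov(x) / (sd_a(x) sd_b(x))`. Values are defined only
#' inside `roi` and where both local standard deviations are meaningfully
#' positive; elsewhere the map is `NA`. The near-flat threshold is
#' `tau = 1e-6 * s^2` where `s` is the geometric mean of the two ROI-wide
#' intensity standard deviations, so the rule is invariant to global intensity
#' rescaling.
#'
#' @param target,mapped [vx_volume]s on the same grid.
#' @param roi [vx_mask] with at least one foreground voxel.
#' @param sigma_g Gaussian window standard deviation in voxels (default 2).
#' @return A `vx_simmap`: list with `values` (3D array, `NA` = undefined),
#'   `sigma_g`, and optional `atlas_id`/`condition` tags.
#' @export
lncc <- function(target, mapped, roi, sigma_g = 2) {
  stopifnot(is_vx_volume(target), is_vx_volume(mapped), is_vx_mask(roi))
  check_same_geometry(target, mapped, "lncc images")
  check_same_geometry(target, roi, "image and roi")
  if (!any(roi$data)) stop("empty roi")
  mom <- local_moments(target, mapped, sigma_g)
  s_t <- stats::sd(target$data[roi$data])
  s_m <- stats::sd(mapped$data[roi$data])
  tau <- 1e-6 * s_t * s_m
  denom <- mom$sd_a * mom$sd_b
  vals <- array(NA_real_, dim = dim(target$data))
  ok <- roi$data & denom > tau
  vals[ok] <- mom$cov[ok] / denom[ok]
  # numerical guard: |cov| <= sd_a*sd_b can overshoot by rounding
  vals[ok] <- pmin(pmax(vals[ok], -1), 1)
  structure(list(values = vals, sigma_g = sigma_g,
                 atlas_id = NA_character_, condition = NA_character_),
            class = "vx_simmap")
}

#' Standard-score (z) normalisation over an ROI
#'
#' Subtracts the ROI mean and divides by the ROI population standard
#' deviation; the same affine map is applied to voxels outside the ROI.
#'
#' @param v a [vx_volume].
#' @param roi a [vx_mask]; intensities inside it must not be constant.
#' @return A [vx_volume] whose ROI voxels have mean 0 and population sd 1.
#' @export
zscore <- function(v, roi) {
  stopifnot(is_vx_volume(v), is_vx_mask(roi))
  check_same_geometry(v, roi, "image and roi")
  x <- v$data[roi$data]
  if (length(x) == 0L) stop("empty roi")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev <= 0) stop("zero intensity variance inside roi")
  vx_volume((v$data - mu) / sdev, spacing = v$spacing, origin = v$origin)
}

#' Global normalised correlation coefficient over an ROI
#'
#' Pearson correlation of the two voxel-value vectors restricted to the ROI.
#'
#' @inheritParams lncc
#' @param a,b [vx_volume]s on the same grid.
#' @return A scalar in `[-1, 1]`.
#' @export
global_ncc <- function(a, b, roi) {
  stopifnot(is_vx_volume(a), is_vx_volume(b), is_vx_mask(roi))
  check_same_geometry(a, b, "ncc images")
  x <- a$data[roi$data]
  y <- b$data[roi$data]
  if (length(x) < 2L) stop("roi too small for correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input within roi")
  stats::cor(x, y)
}
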