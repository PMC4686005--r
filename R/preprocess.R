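# Rough organ-mask extraction and the mask-fusion / ROI logic. These masks
# feed the registration ROI and the similarity ROI; they are deliberately
# coarse and are never treated as an anatomical segmentation.

#' Otsu threshold of a numeric vector
#'
#' Exhaustive search over a fixed-bin histogram for the threshold maximising
#' the between-class variance. Returns a threshold on the intensity scale;
#' values strictly above it form the high class.
#'
#' @param x numeric vector with at least two distinct values.
#' @param nbins number of histogram bins (default 256).
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("Otsu threshold undefined for a constant image")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                          nbins), nbins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  # between-class variance for a cut after bin k
  w0k <- w0[-nbins]
  mu0k <- mu0[-nbins]
  valid <- w0k > 0 & w0k < 1
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mu_t * w0k[valid] - mu0k[valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  k <- which.max(bcv)
  edges[k + 1L]
}

#' Rough foreground mask from intensity
#'
#' Otsu thresholding (bright class = foreground), largest connected component
#' (26-connectivity) after discarding components smaller than
#' `min_component_voxels`, morphological closing with a ball structuring
#' element, then interior hole filling.
#'
#' @param v a [vx_volume] with non-constant intensities.
#' @param min_component_voxels components below this size are discarded
#'   before the largest is kept (default 100).
#' @param closing_radius ball radius in voxels for closing (default 3).
#' @return A [vx_mask].
#' @export
rough_mask <- function(v, min_component_voxels = 100, closing_radius = 3) {
  stopifnot(is_vx_volume(v))
  thr <- otsu_threshold(as.numeric(v$data))
  fg <- v$data > thr
  labs <- connected_components(fg, 26)
  sizes <- tabulate(labs[labs > 0L])
  keep <- which(sizes >= min_component_voxels)
  if (length(keep) == 0L) keep <- which.max(sizes)
  best <- keep[which.max(sizes[keep])]
  m <- labs == best
  if (closing_radius > 0) m <- close_ball(m, closing_radius)
  m <- fill_holes(m)
  vx_mask(m, spacing = v$spacing, origin = v$origin)
}

#' Majority-vote fusion of binary masks
#'
#' A voxel is foreground iff the fraction of masks voting foreground is at
#' least `threshold`; the fraction is evaluated in exact arithmetic, so a
#' boundary case such as 16/20 at threshold 0.8 is foreground.
#'
#' @param masks non-empty list of [vx_mask]s sharing geometry.
#' @param threshold fraction in (0, 1].
#' @return A [vx_mask].
#' @export
fuse_masks <- function(masks, threshold) {
  if (length(masks) == 0L) stop("no masks to fuse")
  stopifnot(all(vapply(masks, is_vx_mask, logical(1))),
            threshold > 0, threshold <= 1)
  for (m in masks[-1]) check_same_geometry(masks[[1]], m, "masks")
  votes <- Reduce(`+`, lapply(masks, function(m) m$data + 0))
  frac <- votes / length(masks)
  vx_mask(frac >= threshold - 1e-12,
          spacing = masks[[1]]$spacing, origin = masks[[1]]$origin)
}

#' Build the per-condition masks and global ROI
#'
#' Fuses the mapped masks of each condition's database with majority voting
#' at `threshold`, then intersects the per-condition masks into the global
#' ROI `M` to which all similarity computation is restricted.
#'
#' @param per_condition_masks named list: condition -> list of [vx_mask]s in
#'   target space (each condition needs at least one).
#' @param threshold fusion threshold (default 0.8, the refined stage).
#' @return A list of class `vx_roiset`: `per_condition` (named list of fused
#'   [vx_mask]s), `roi` (their intersection) and `threshold`.
#' @export
build_roi <- function(per_condition_masks, threshold = 0.8) {
  if (length(per_condition_masks) < 1L) stop("no conditions supplied")
  if (is.null(names(per_condition_masks)) ||
      any(!nzchar(names(per_condition_masks))))
    stop("per_condition_masks must be a named list")
  fused <- lapply(per_condition_masks, fuse_masks, threshold = threshold)
  inter <- Reduce(function(a, b) a & b, lapply(fused, function(m) m$data))
  if (!any(inter))
    stop("databases do not overlap on target: ROI intersection is empty")
  g <- fused[[1]]
  structure(list(per_condition = fused,
                 roi = vx_mask(inter, spacing = g$spacing, origin = g$origin),
                 threshold = threshold),
            class = "vx_roiset")
}
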