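# Voxelwise atlas rating (VoxAR). The per-voxel LNCC of every atlas from
# every database is pooled and ranked; per voxel, the number of top-T
# entries from each condition is counted; a voxel is assigned a condition
# only when that condition's count reaches the absolute-majority guard
# ceil(T/2 + 1), otherwise it stays UNASSIGNED. The percentage histogram of
# the assigned voxels is the diagnostic evidence; its mode is the diagnosis.

#' Pooled cross-database per-voxel ranking
#'
#' Sorts, at every ROI voxel, the LNCC values of all atlases from all
#' databases in descending order and marks the top `T`. Undefined (NA) LNCC
#' entries never enter the top; ties are broken stably by (condition name,
#' atlas index).
#'
#' @param sim_maps named list: condition -> list of `vx_simmap`.
#' @param roi [vx_mask] restricting the computation.
#' @param T number of top atlases rated per voxel (default 7).
#' @return A `vx_pooled`: list with `top` (matrix, ROI voxels x `T`, column
#'   index of each top atlas, 0-padded where fewer than `T` are defined),
#'   `col_condition`, `col_atlas`, `conditions`, `voxel_index`, `dim`, `T`.
#' @export
pool_rank <- function(sim_maps, roi, T = 7) {
  stopifnot(is.list(sim_maps), length(sim_maps) >= 1, !is.null(names(sim_maps)),
            is_vx_mask(roi), T >= 1)
  conds <- sort(names(sim_maps))
  col_condition <- character(0)
  col_atlas <- integer(0)
  maps <- list()
  for (cond in conds) {
    for (k in seq_along(sim_maps[[cond]])) {
      maps[[length(maps) + 1L]] <- sim_maps[[cond]][[k]]
      col_condition <- c(col_condition, cond)
      col_atlas <- c(col_atlas, k)
    }
  }
  if (length(maps) < T)
    warning("only ", length(maps), " atlases pooled but T = ", T)
  idx <- which(roi$data)
  if (length(idx) == 0L) stop("empty roi")
  V <- vapply(maps, function(s) s$values[idx], numeric(length(idx)))
  V <- matrix(V, nrow = length(idx))
  if (all(is.na(V)))
    stop("no defined atlas similarity at any roi voxel")
  structure(list(top = row_top_indices_cpp(V, as.integer(T)),
                 col_condition = col_condition, col_atlas = col_atlas,
                 conditions = conds, voxel_index = idx,
                 dim = dim(roi$data), T = as.integer(T)),
            class = "vx_pooled")
}

#' Per-voxel condition counts among the top-T
#'
#' @param p a `vx_pooled` from [pool_rank()].
#' @return A `vx_counts`: list with `counts` (integer matrix, ROI voxels x
#'   conditions), `defined` (number of defined atlases per voxel capped at
#'   `T`), plus the pooling metadata.
#' @export
count_conditions <- function(p) {
  stopifnot(inherits(p, "vx_pooled"))
  cond_idx <- match(p$col_condition, p$conditions)
  top_cond <- matrix(NA_integer_, nrow(p$top), ncol(p$top))
  nz <- p$top > 0L
  top_cond[nz] <- cond_idx[p$top[nz]]
  counts <- vapply(seq_along(p$conditions), function(ci)
    rowSums(top_cond == ci, na.rm = TRUE), numeric(nrow(p$top)))
  counts <- matrix(as.integer(counts), nrow = nrow(p$top),
                   dimnames = list(NULL, p$conditions))
  structure(list(counts = counts, defined = as.integer(rowSums(nz)),
                 conditions = p$conditions, voxel_index = p$voxel_index,
                 dim = p$dim, T = p$T),
            class = "vx_counts")
}

#' Absolute-majority threshold for the rating map
#'
#' The guard printed with the rating rule: `ceil(T/2 + 1)` (T = 7 gives 5).
#'
#' @param T pooled top size.
#' @return Integer threshold.
#' @export
majority_threshold <- function(T) {
  as.integer(ceiling(T / 2 + 1))
}

#' Build the rating map from condition counts
#'
#' A voxel is assigned `argmax` of the counts when the maximal count reaches
#' the absolute-majority guard, else it stays UNASSIGNED (code 0). Because
#' the guard exceeds `T/2`, an assigned voxel's maximal count is always a
#' strict unique maximum.
#'
#' @param counts a `vx_counts` from [count_conditions()].
#' @param T pooled top size (defaults to the one recorded in `counts`).
#' @param threshold override for the majority guard (default
#'   [majority_threshold()] of `T`).
#' @return A `vx_ratingmap`: list with `codes` (3D integer array: `NA`
#'   outside ROI, 0 = UNASSIGNED, i = i-th condition), `conditions`,
#'   `threshold`, `T`.
#' @export
build_rating_map <- function(counts, T = counts$T, threshold = NULL) {
  stopifnot(inherits(counts, "vx_counts"))
  if (is.null(threshold)) threshold <- majority_threshold(T)
  cm <- counts$counts
  maxc <- do.call(pmax, as.data.frame(cm))
  arg <- max.col(cm, ties.method = "first")
  assigned <- maxc >= threshold
  codes3d <- array(NA_integer_, dim = counts$dim)
  codes3d[counts$voxel_index] <- ifelse(assigned, arg, 0L)
  structure(list(codes = codes3d, conditions = counts$conditions,
                 threshold = as.integer(threshold), T = as.integer(T)),
            class = "vx_ratingmap")
}

#' Rating histogram of an assigned rating map
#'
#' Percentage of assigned (non-UNASSIGNED) voxels per condition; the
#' separation score is the gap between the top two percentages and serves as
#' a confidence proxy.
#'
#' @param r a `vx_ratingmap`.
#' @return A `vx_histogram`: list with `percent` (named list over
#'   conditions; empty when no voxel is assigned), `n_assigned`,
#'   `n_unassigned`, `separation`.
#' @export
rating_histogram <- function(r) {
  stopifnot(inherits(r, "vx_ratingmap"))
  codes <- r$codes[!is.na(r$codes)]
  n_un <- sum(codes == 0L)
  assigned <- codes[codes > 0L]
  if (length(assigned) == 0L) {
    warning("all voxels unassigned: empty rating histogram")
    return(structure(list(percent = stats::setNames(list(), character(0)),
                          n_assigned = 0L, n_unassigned = n_un,
                          separation = NA_real_),
                     class = "vx_histogram"))
  }
  tab <- tabulate(assigned, nbins = length(r$conditions))
  pct <- 100 * tab / length(assigned)
  names(pct) <- r$conditions
  srt <- sort(pct, decreasing = TRUE)
  sep <- if (length(srt) >= 2) srt[1] - srt[2] else srt[1]
  structure(list(percent = as.list(pct),
                 n_assigned = length(assigned), n_unassigned = n_un,
                 separation = unname(sep)),
            class = "vx_histogram")
}

#' VoxAR diagnosis
#'
#' Composes LNCC -> pooled ranking -> condition counts -> rating map ->
#' rating histogram and assigns the condition with the highest percentage.
#' If no voxel passes the absolute-majority guard the diagnosis is refused
#' (`refused = TRUE`, `diagnosis = NULL`).
#'
#' @param target the target [vx_volume].
#' @param databases_mapped named list: condition -> list of
#'   `vx_mapped_atlas` in target space (>= 2 conditions).
#' @param roi the global ROI [vx_mask].
#' @param T pooled top size (default 7).
#' @param sigma_g LNCC Gaussian window sd in voxels (default 2).
#' @param threshold majority-guard override (default `ceil(T/2 + 1)`).
#' @return A `vx_report` with the rating histogram and the parameters used.
#'   To retain the rating map itself, compose [lncc()], [pool_rank()],
#'   [count_conditions()] and [build_rating_map()] directly.
#' @export
voxar_diagnose <- function(target, databases_mapped, roi, T = 7, sigma_g = 2,
                           threshold = NULL) {
  stopifnot(length(databases_mapped) >= 2, is_vx_volume(target),
            is_vx_mask(roi))
  sims <- lapply(databases_mapped, function(db)
    lapply(db, function(a) lncc(target, a$image, roi, sigma_g)))
  pooled <- pool_rank(sims, roi, T)
  counts <- count_conditions(pooled)
  rmap <- build_rating_map(counts, T, threshold)
  hist <- suppressWarnings(rating_histogram(rmap))
  params <- list(T = T, sigma_g = sigma_g,
                 threshold = rmap$threshold,
                 threshold_is_default = is.null(threshold))
  if (hist$n_assigned == 0L) {
    return(structure(list(method = "VoxAR", diagnosis = NULL, refused = TRUE,
                          histogram = hist, parameters = params,
                          warnings = "all voxels unassigned; diagnosis refused"),
                     class = "vx_report"))
  }
  pct <- unlist(hist$percent)
  structure(list(method = "VoxAR",
                 diagnosis = names(pct)[which.max(pct)],
                 refused = FALSE,
                 histogram = hist,
                 parameters = params,
                 warnings = character(0)),
            class = "vx_report")
}
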