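# Image Synthesis Approach (ISA): for each condition's database, the
# per-voxel LNCC of its atlases is ranked (within the database), ranks decay
# exponentially into weights, and a synthetic image is fused as the weighted
# average of the z-scored atlas intensities. The condition whose synthetic
# image best matches the target under global NCC is the diagnosis.

#' Per-voxel LNCC ranks within one database
#'
#' At each ROI voxel the defined LNCC values are ranked in descending order
#' (most similar atlas gets rank 0); ties keep atlas list order. Voxels where
#' an atlas's LNCC is undefined get `NA` for that atlas and the remaining
#' atlases are ranked among themselves.
#'
#' @param sim_maps list of `vx_simmap` for the atlases of one database.
#' @param roi [vx_mask] restricting the computation.
#' @return A `vx_rankfield`: list with `ranks` (matrix, ROI voxels x
#'   atlases, 0-based, `NA` = undefined), `voxel_index`, `dim`.
#' @export
rank_in_database <- function(sim_maps, roi) {
  stopifnot(length(sim_maps) >= 1, is_vx_mask(roi))
  idx <- which(roi$data)
  V <- vapply(sim_maps, function(s) s$values[idx], numeric(length(idx)))
  V <- matrix(V, nrow = length(idx))
  if (all(is.na(V)))
    stop("all similarity maps are undefined at every roi voxel")
  structure(list(ranks = row_ranks_desc_cpp(V),
                 voxel_index = idx, dim = dim(roi$data)),
            class = "vx_rankfield")
}

#' Exponential rank-decay weights
#'
#' `alpha = exp(-beta * rank)`; undefined (NA) ranks get weight 0. The best
#' atlas (rank 0) has weight 1.
#'
#' @param r a `vx_rankfield`.
#' @param beta decay rate (> 0, default 0.5).
#' @return Numeric matrix of weights, same shape as `r$ranks`.
#' @export
ranks_to_weights <- function(r, beta = 0.5) {
  stopifnot(inherits(r, "vx_rankfield"), beta > 0)
  w <- exp(-beta * r$ranks)
  w[is.na(w)] <- 0
  w
}

#' Fuse mapped atlases into a synthetic image
#'
#' Weighted average of the z-scored atlas intensities, voxel by voxel:
#' `I_syn(x) = sum_n alpha_n(x) J_n(x) / sum_n alpha_n(x)`. Voxels with zero
#' total weight are flagged undefined.
#'
#' @param mapped list of `vx_mapped_atlas` for one condition.
#' @param weights weight matrix from [ranks_to_weights()] (ROI voxels x
#'   atlases, same atlas order as `mapped`).
#' @param roi the global ROI [vx_mask] (z-scoring reference).
#' @return A `vx_synth`: list with `condition`, `values` (3D array, defined
#'   on the ROI, `NA` elsewhere/undefined), `ncc` (filled by
#'   [isa_diagnose()]).
#' @export
synthesize <- function(mapped, weights, roi) {
  stopifnot(length(mapped) >= 1, is_vx_mask(roi),
            ncol(weights) == length(mapped))
  idx <- which(roi$data)
  stopifnot(nrow(weights) == length(idx))
  J <- vapply(mapped, function(a) zscore(a$image, roi)$data[idx],
              numeric(length(idx)))
  J <- matrix(J, nrow = length(idx))
  wsum <- rowSums(weights)
  fused <- rep(NA_real_, length(idx))
  ok <- wsum > 0
  if (!any(ok)) stop("zero total fusion weight at every roi voxel")
  fused[ok] <- rowSums(weights * J)[ok] / wsum[ok]
  vals <- array(NA_real_, dim = dim(roi$data))
  vals[idx] <- fused
  structure(list(condition = mapped[[1]]$condition, values = vals,
                 ncc = NA_real_),
            class = "vx_synth")
}

#' ISA diagnosis
#'
#' Builds one synthetic image per condition, scores each against the
#' z-scored target with global NCC over the ROI, and assigns the condition of
#' the top-ranked synthetic image. Exact NCC ties are broken by condition
#' name order and flagged in the report.
#'
#' @param databases_mapped named list: condition -> list of
#'   `vx_mapped_atlas` in target space.
#' @param target the target [vx_volume].
#' @param roi the global ROI [vx_mask].
#' @param beta rank-decay rate (default 0.5).
#' @param sigma_g LNCC Gaussian window sd in voxels (default 2).
#' @return A `vx_report` with per-condition NCC scores.
#' @export
isa_diagnose <- function(databases_mapped, target, roi, beta = 0.5,
                         sigma_g = 2) {
  stopifnot(length(databases_mapped) >= 2, is_vx_volume(target),
            is_vx_mask(roi))
  conds <- sort(names(databases_mapped))
  target_z <- zscore(target, roi)
  idx <- which(roi$data)
  scores <- numeric(0)
  warnings_out <- character(0)
  for (cond in conds) {
    mapped <- databases_mapped[[cond]]
    sims <- lapply(mapped, function(a) lncc(target, a$image, roi, sigma_g))
    rf <- rank_in_database(sims, roi)
    w <- ranks_to_weights(rf, beta)
    syn <- synthesize(mapped, w, roi)
    def <- !is.na(syn$values[idx])
    x <- target_z$data[idx][def]
    y <- syn$values[idx][def]
    scores[cond] <- stats::cor(x, y)
  }
  best <- max(scores)
  winners <- conds[scores >= best - 1e-12]
  if (length(winners) > 1L)
    warnings_out <- c(warnings_out,
                      paste0("NCC tie between: ",
                             paste(winners, collapse = ", "),
                             "; broken by condition-name order"))
  structure(list(method = "ISA",
                 diagnosis = winners[1],
                 refused = FALSE,
                 ncc_scores = as.list(scores),
                 parameters = list(beta = beta, sigma_g = sigma_g),
                 warnings = warnings_out),
            class = "vx_report")
}
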