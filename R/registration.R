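# Two-stage atlas-to-target mapping behind a backend adapter. The package
# registers atlas -> target directly (so mapped masks land in target space
# without transform inversion). Backends:
#   identity       resample-only; atlases assumed pre-aligned on the target
#                  grid (the phantom-cohort setting)
#   builtin_affine 12-parameter affine maximising NCC by multi-resolution
#                  gradient-free search; images resampled trilinearly, masks
#                  nearest-neighbour
#   external       subprocess contract for a full deformable engine; stage
#                  parameters (coarse-to-fine levels, iteration caps, bending
#                  energy, NMI metric) are carried in the config verbatim

#' Registration configuration
#'
#' Carries the backend choice and the standard two-stage parameter block:
#' stage 1 is rigid then affine, stage 2 non-rigid (external backend only).
#'
#' @param backend one of `"identity"`, `"builtin_affine"`, `"external"`.
#' @param rigid_levels,rigid_iterations coarse-to-fine levels / iteration cap
#'   for the rigid part of stage 1 (defaults 3 / 5).
#' @param affine_levels,affine_iterations stage-1 affine counterpart
#'   (defaults 3 / 8).
#' @param nonrigid_levels,nonrigid_iterations,bending_energy stage-2
#'   free-form-deformation block, used only by the external backend
#'   (defaults 3 / 300 / 0.005).
#' @param nonrigid_metric similarity metric name handed to the external
#'   engine (default `"NMI"`).
#' @param external_command command template with placeholders `{ref}`,
#'   `{flo}`, `{mask}`, `{out}`; run once for the intensity image and once
#'   for the mask.
#' @return A list of class `vx_regconfig`.
#' @export
registration_config <- function(backend = c("identity", "builtin_affine", "external"),
                                rigid_levels = 3, rigid_iterations = 5,
                                affine_levels = 3, affine_iterations = 8,
                                nonrigid_levels = 3, nonrigid_iterations = 300,
                                bending_energy = 0.005,
                                nonrigid_metric = "NMI",
                                external_command = NULL) {
  backend <- match.arg(backend)
  stopifnot(rigid_iterations >= 1, affine_iterations >= 1,
            nonrigid_iterations >= 1, bending_energy >= 0)
  if (backend == "external" && is.null(external_command))
    stop("external backend requires external_command")
  structure(list(backend = backend,
                 rigid_levels = rigid_levels,
                 rigid_iterations = rigid_iterations,
                 affine_levels = affine_levels,
                 affine_iterations = affine_iterations,
                 nonrigid_levels = nonrigid_levels,
                 nonrigid_iterations = nonrigid_iterations,
                 bending_energy = bending_energy,
                 nonrigid_metric = nonrigid_metric,
                 external_command = external_command),
            class = "vx_regconfig")
}

# 12-parameter affine matrix: translation (voxels), rotation (radians),
# log-scale, shear. Applied about the grid centre.
#' @keywords internal
affine_matrix <- function(par) {
  t_ <- par[1:3]; r <- par[4:6]; s <- exp(par[7:9]); sh <- par[10:12]
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  S <- diag(s)
  Sh <- rbind(c(1, sh[1], sh[2]), c(0, 1, sh[3]), c(0, 0, 1))
  list(M = Rz %*% Ry %*% Rx %*% S %*% Sh, t = t_)
}

# All voxel coordinates of a grid (0-based), as an n x 3 matrix.
#' @keywords internal
grid_coords <- function(d) {
  cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
        rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

# Map 0-based target voxel coords to atlas voxel coords under `par`.
#' @keywords internal
apply_affine <- function(coords, par, center) {
  af <- affine_matrix(par)
  sweep(t(af$M %*% t(sweep(coords, 2, center))), 2, -(center + af$t))
}

# Resample a volume under an affine (trilinear) on the target grid.
#' @keywords internal
resample_affine_volume <- function(v, par, target_dim, outside) {
  center <- (target_dim - 1) / 2
  coords <- apply_affine(grid_coords(target_dim), par, center)
  vals <- sample_trilinear_cpp(as.numeric(v$data), as.integer(dim(v$data)),
                               coords, outside)
  array(vals, dim = target_dim)
}

#' @keywords internal
resample_affine_mask <- function(m, par, target_dim) {
  center <- (target_dim - 1) / 2
  coords <- apply_affine(grid_coords(target_dim), par, center)
  vals <- sample_nearest_cpp(as.numeric(m$data), as.integer(dim(m$data)),
                             coords, 0)
  array(vals > 0.5, dim = target_dim)
}

# NCC objective between the target and the atlas resampled under `par`,
# evaluated on a strided subset of (ROI) voxels; NA samples are dropped.
#' @keywords internal
affine_ncc <- function(par, atlas_data, atlas_dim, target_data, target_dim,
                       eval_idx, eval_coords, center) {
  coords <- apply_affine(eval_coords, par, center)
  vals <- sample_trilinear_cpp(atlas_data, atlas_dim, coords, NA_real_)
  ok <- !is.na(vals)
  if (sum(ok) < 50) return(-Inf)
  x <- target_data[eval_idx[ok]]
  y <- vals[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(-Inf)
  stats::cor(x, y)
}

# Multi-resolution gradient-free affine search (Nelder-Mead per block).
#' @keywords internal
builtin_affine_fit <- function(atlas, target, target_roi = NULL, cfg) {
  td <- dim(target$data)
  center <- (td - 1) / 2
  atlas_data <- as.numeric(atlas$data)
  atlas_dim <- as.integer(dim(atlas$data))
  roi_flag <- if (is.null(target_roi)) array(TRUE, td) else target_roi$data
  par <- rep(0, 12)
  strides <- pmax(2^((cfg$affine_levels - 1):0), 1)
  parscale <- c(rep(1, 3), rep(0.05, 3), rep(0.05, 3), rep(0.05, 3))
  for (stride in strides) {
    idx <- which(roi_flag)
    keep <- rep(FALSE, length(idx))
    co <- grid_coords(td)[idx, , drop = FALSE]
    keep <- (co[, 1] %% stride == 0) & (co[, 2] %% stride == 0) &
      (co[, 3] %% stride == 0)
    eval_idx <- idx[keep]
    eval_coords <- co[keep, , drop = FALSE]
    if (length(eval_idx) < 100) next
    obj <- function(p, active) {
      full <- par
      full[active] <- p
      -affine_ncc(full, atlas_data, atlas_dim, as.numeric(target$data),
                  td, eval_idx, eval_coords, center)
    }
    # translation warm start, then rigid, then full affine
    blocks <- list(1:3, 1:6, 1:12)
    iters <- c(cfg$rigid_iterations, cfg$rigid_iterations, cfg$affine_iterations)
    for (b in seq_along(blocks)) {
      active <- blocks[[b]]
      fit <- stats::optim(par[active], obj, active = active,
                          method = "Nelder-Mead",
                          control = list(maxit = 60 * iters[b],
                                         parscale = parscale[active],
                                         reltol = 1e-7))
      par[active] <- fit$par
    }
  }
  final <- affine_ncc(par, atlas_data, atlas_dim, as.numeric(target$data), td,
                      which(roi_flag), grid_coords(td)[which(roi_flag), ,
                                                       drop = FALSE], center)
  ident <- affine_ncc(rep(0, 12), atlas_data, atlas_dim,
                      as.numeric(target$data), td, which(roi_flag),
                      grid_coords(td)[which(roi_flag), , drop = FALSE], center)
  if (!is.finite(final) || final <= ident) {
    warning("affine optimisation did not improve over identity; falling back")
    par <- rep(0, 12)
  }
  par
}

#' @keywords internal
atlas_background <- function(v) {
  d <- dim(v$data)
  stats::median(v$data[c(1, d[1]), c(1, d[2]), c(1, d[3])])
}

#' Map one atlas (image + mask) into target space
#'
#' @param atlas_image a [vx_volume].
#' @param atlas_mask its paired [vx_mask].
#' @param target the target [vx_volume].
#' @param target_roi optional [vx_mask] restricting the similarity evaluation
#'   (stage-2 masking).
#' @param cfg a [registration_config()].
#' @return A `vx_mapped_atlas`: list with `condition`, `id`,
#'   `image` ([vx_volume] in target geometry), `mask` ([vx_mask]),
#'   `provenance` (backend + parameters).
#' @export
register_atlas <- function(atlas_image, atlas_mask, target, target_roi = NULL,
                           cfg = registration_config("identity")) {
  stopifnot(is_vx_volume(atlas_image), is_vx_mask(atlas_mask),
            is_vx_volume(target))
  check_same_geometry(atlas_image, atlas_mask, "atlas image and mask")
  if (stats::sd(target$data) == 0) stop("constant target image")
  td <- dim(target$data)
  if (cfg$backend == "identity") {
    check_same_geometry(atlas_image, target, "identity-backend atlas and target")
    out <- list(image = atlas_image, mask = atlas_mask,
                provenance = list(backend = "identity"))
  } else if (cfg$backend == "builtin_affine") {
    par <- builtin_affine_fit(atlas_image, target, target_roi, cfg)
    img <- resample_affine_volume(atlas_image, par, td,
                                  outside = atlas_background(atlas_image))
    msk <- resample_affine_mask(atlas_mask, par, td)
    out <- list(image = vx_volume(img, target$spacing, target$origin),
                mask = vx_mask(msk, target$spacing, target$origin),
                provenance = list(backend = "builtin_affine", par = par))
  } else {
    out <- external_register(atlas_image, atlas_mask, target, target_roi, cfg)
  }
  if (!any(out$mask$data)) stop("mapped atlas mask is empty")
  structure(c(out, list(condition = NA_character_, id = NA_character_)),
            class = "vx_mapped_atlas")
}

# Subprocess contract: the command template is instantiated once for the
# intensity image and once for the mask; outputs must be NIfTI on the target
# grid.
#' @keywords internal
external_register <- function(atlas_image, atlas_mask, target, target_roi, cfg) {
  tmp <- tempfile("voxar_reg_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  ref <- file.path(tmp, "ref.nii.gz")
  write_volume(target, ref)
  mask_path <- file.path(tmp, "roi.nii.gz")
  if (!is.null(target_roi)) write_mask(target_roi, mask_path) else mask_path <- ""
  run_one <- function(flo_obj, out_name, is_mask) {
    flo <- file.path(tmp, paste0("flo_", out_name))
    out <- file.path(tmp, paste0("out_", out_name))
    if (is_mask) write_mask(flo_obj, flo) else write_volume(flo_obj, flo)
    cmd <- cfg$external_command
    cmd <- gsub("{ref}", ref, cmd, fixed = TRUE)
    cmd <- gsub("{flo}", flo, cmd, fixed = TRUE)
    cmd <- gsub("{mask}", mask_path, cmd, fixed = TRUE)
    cmd <- gsub("{out}", out, cmd, fixed = TRUE)
    status <- system(cmd, intern = FALSE)
    if (status != 0 || !file.exists(out))
      stop("external registration command failed (exit ", status, "): ", cmd)
    if (is_mask) read_mask(out) else read_volume(out)
  }
  img <- run_one(atlas_image, "img.nii.gz", FALSE)
  msk <- run_one(atlas_mask, "mask.nii.gz", TRUE)
  check_same_geometry(img, target, "external output and target")
  list(image = img, mask = msk,
       provenance = list(backend = "external", command = cfg$external_command,
                         nonrigid = cfg[c("nonrigid_levels",
                                          "nonrigid_iterations",
                                          "bending_energy",
                                          "nonrigid_metric")]))
}

#' Map all atlas databases to a target
#'
#' Stage 1 maps every atlas mask into target space (affine or identity) and
#' fuses them with simple majority voting (threshold 0.5) into a rough target
#' mask; stage 2 re-runs the mapping with the target restricted to that rough
#' mask. Per-atlas failures are warned about and the atlas dropped; a
#' database losing all its atlases is an error.
#'
#' @param databases named list: condition -> list of atlases, each a list
#'   with elements `image` ([vx_volume]), `mask` ([vx_mask]) and optional
#'   `id`.
#' @param target the target [vx_volume].
#' @param cfg a [registration_config()].
#' @return List with `mapped` (condition -> list of `vx_mapped_atlas`) and
#'   `rough_mask` (the fused stage-1 [vx_mask]).
#' @export
map_all <- function(databases, target, cfg = registration_config("identity")) {
  stopifnot(length(databases) >= 1, !is.null(names(databases)))
  if (any(vapply(databases, length, integer(1)) == 0L))
    stop("every database must be non-empty")
  stage1 <- list()
  for (cond in names(databases)) {
    for (k in seq_along(databases[[cond]])) {
      a <- databases[[cond]][[k]]
      res <- tryCatch(
        register_atlas(a$image, a$mask, target, NULL, cfg),
        error = function(e) {
          warning("stage-1 mapping failed for atlas ", cond, "/", k, ": ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(res)) {
        res$condition <- cond
        res$id <- if (!is.null(a$id)) a$id else paste0(cond, "_", k)
        res$.index <- k
        stage1[[length(stage1) + 1L]] <- res
      }
    }
  }
  if (length(stage1) == 0L) stop("all atlases failed stage-1 mapping")
  rough <- fuse_masks(lapply(stage1, `[[`, "mask"), threshold = 0.5)
  if (cfg$backend == "identity") {
    mapped <- split(stage1, vapply(stage1, `[[`, character(1), "condition"))
  } else {
    stage2 <- list()
    for (s in stage1) {
      orig <- databases[[s$condition]][[s$.index]]
      res <- tryCatch(
        register_atlas(orig$image, orig$mask, target, rough, cfg),
        error = function(e) {
          warning("stage-2 mapping failed for atlas ", s$id, ": ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(res)) {
        res$condition <- s$condition
        res$id <- s$id
        stage2[[length(stage2) + 1L]] <- res
      }
    }
    mapped <- split(stage2, vapply(stage2, `[[`, character(1), "condition"))
  }
  lost <- setdiff(names(databases), names(mapped))
  if (length(lost))
    stop("database(s) lost all atlases during mapping: ",
         paste(lost, collapse = ", "))
  mapped <- mapped[names(databases)[names(databases) %in% names(mapped)]]
  list(mapped = mapped, rough_mask = rough)
}
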