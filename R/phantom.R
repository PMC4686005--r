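# Synthetic multi-condition 3D phantoms. Each subject is a condition-specific
# structural template (a large body ellipsoid shared by all conditions plus
# two small tube-like "vessels" whose spatial arrangement differs by
# condition), warped by a random smooth displacement field, modulated by a
# smooth multiplicative bias field, with additive Gaussian noise on a nonzero
# background. The design concentrates the between-condition signal in the
# small vessel region while the bulk anatomy is condition-neutral — the
# regime the rating method targets: local similarity separates conditions,
# global appearance barely does.

#' Phantom cohort specification
#'
#' Morphology library (per condition):
#' * `normal`    — two parallel vessels leaving the top of the body at the
#'   usual position.
#' * `switch_a`  — the two vessels crossed (swap sides along their course),
#'   emulating the translocation of an arterial-switch repair.
#' * `switch_b`  — vessels parallel but anteriorly displaced (the vessels
#'   stay transposed after an atrial-switch repair), plus a connecting slab
#'   (the intra-atrial baffle).
#' * `fallot`    — a single wide vessel displaced to one side (a novel
#'   morphology used as the "missing pathology" probe).
#'
#' @param grid integer length-3, voxels per axis (each >= 24; default 48).
#' @param conditions character vector (>= 2) drawn from the morphology
#'   library above.
#' @param deformation_amplitude RMS displacement in voxels (per component) of
#'   the random smooth warp applied per subject (default 1, the scale of the
#'   residual misalignment left after non-rigid inter-subject registration —
#'   the regime the identity-registration experiments emulate).
#' @param deformation_smoothness Gaussian smoothing sigma in voxels of the
#'   displacement field (default 5).
#' @param noise_sd additive Gaussian noise standard deviation in intensity
#'   units (default 8; structure/background contrast is 80, so default
#'   SNR = 10).
#' @param bias_amplitude relative amplitude of the smooth multiplicative
#'   intensity bias field (default 0.1).
#' @param spacing voxel size in mm (default iso 1.5).
#' @return A list of class `vx_phantom_spec`.
#' @export
phantom_spec <- function(grid = c(48, 48, 48),
                         conditions = c("normal", "switch_a", "switch_b"),
                         deformation_amplitude = 1,
                         deformation_smoothness = 5,
                         noise_sd = 8,
                         bias_amplitude = 0.1,
                         spacing = c(1.5, 1.5, 1.5)) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 24L),
            length(conditions) >= 1L, !anyDuplicated(conditions),
            deformation_amplitude >= 0, deformation_smoothness > 0,
            noise_sd >= 0, bias_amplitude >= 0)
  unknown <- setdiff(conditions, names(condition_library()))
  if (length(unknown))
    stop("unknown condition(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(condition_library()), collapse = ", "))
  structure(list(grid = grid, conditions = conditions,
                 deformation_amplitude = deformation_amplitude,
                 deformation_smoothness = deformation_smoothness,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 spacing = as.numeric(spacing)),
            class = "vx_phantom_spec")
}

# Structural parameters per condition, in grid-relative units. Vessel
# arrangements are pairwise distinct; the body ellipsoid is shared.
#' @keywords internal
condition_library <- function() {
  list(
    normal   = list(cross = FALSE, slab = FALSE, wide = FALSE, ty = 0.46),
    switch_a = list(cross = TRUE,  slab = FALSE, wide = FALSE, ty = 0.46),
    switch_b = list(cross = FALSE, slab = TRUE,  wide = FALSE, ty = 0.56),
    fallot   = list(cross = FALSE, slab = FALSE, wide = TRUE,  ty = 0.46)
  )
}

# Intensity levels (arbitrary units). Background is nonzero so rough-mask
# extraction is nontrivial.
.vx_levels <- list(background = 20, body = 100, vessel = 160, slab = 130)

# Deterministic structural template + exact support mask for one condition.
#' @keywords internal
phantom_template <- function(spec, condition) {
  p <- condition_library()[[condition]]
  if (is.null(p)) stop("condition not in the morphology library: ", condition)
  d <- spec$grid
  x <- (seq_len(d[1]) - 1) / (d[1] - 1)
  y <- (seq_len(d[2]) - 1) / (d[2] - 1)
  z <- (seq_len(d[3]) - 1) / (d[3] - 1)
  X <- array(rep(x, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(z, each = d[1] * d[2]), dim = d)

  # body ellipsoid: centre slightly low so vessels can exit the top
  body <- ((X - 0.5) / 0.33)^2 + ((Y - 0.5) / 0.30)^2 +
    ((Z - 0.42) / 0.30)^2 <= 1

  # vessels: tubes along z through the upper half; great vessels are gross
  # structures, so the radius is ~7.5% of the grid
  rad <- 0.075
  zlo <- 0.35; zhi <- 0.95
  tz <- pmin(pmax((Z - zlo) / (zhi - zlo), 0), 1)
  dx <- 0.15
  if (p$cross) {
    cx1 <- 0.5 - dx + 2 * dx * tz     # left -> right
    cx2 <- 0.5 + dx - 2 * dx * tz     # right -> left
  } else {
    cx1 <- 0.5 - dx + 0 * tz
    cx2 <- 0.5 + dx + 0 * tz
  }
  r1 <- if (p$wide) rad * 1.6 else rad
  in_z <- Z >= zlo & Z <= zhi
  off1 <- if (p$wide) 0.06 else 0
  ty <- p$ty
  tube1 <- in_z & ((X - (cx1 + off1))^2 + (Y - ty)^2 <= r1^2)
  tube2 <- if (p$wide) {
    in_z & ((X - (cx2 + off1))^2 + (Y - (ty + 0.12))^2 <= (rad * 0.6)^2)
  } else {
    in_z & ((X - cx2)^2 + (Y - ty)^2 <= rad^2)
  }
  slab <- if (p$slab) {
    abs(Y - ty) <= 0.05 & X >= 0.5 - dx & X <= 0.5 + dx &
      Z >= 0.50 & Z <= 0.75
  } else {
    array(FALSE, dim = d)
  }

  raw <- array(.vx_levels$background, dim = d)
  raw[body] <- .vx_levels$body
  raw[slab] <- .vx_levels$slab
  raw[tube1 | tube2] <- .vx_levels$vessel
  support <- body | tube1 | tube2 | slab
  list(image = gauss_smooth(raw, sigma = 1), support = support)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Smooth unit-RMS random field.
#' @keywords internal
smooth_noise_field <- function(d, sigma) {
  f <- gauss_smooth(array(stats::rnorm(prod(d)), dim = d), sigma)
  f / sqrt(mean(f^2))
}

#' Generate one phantom subject
#'
#' Deterministic for a fixed `(spec, condition, seed)`. The image is the
#' condition template warped by a random smooth displacement field, scaled by
#' a smooth multiplicative bias field, plus Gaussian noise; the true mask is
#' the warped structural support.
#'
#' @param spec a [phantom_spec()].
#' @param condition one of `spec$conditions`.
#' @param seed integer seed for this subject.
#' @return A `vx_subject`: list with `id`, `condition`, `image`
#'   ([vx_volume]) and `true_mask` ([vx_mask]).
#' @export
generate_subject <- function(spec, condition, seed) {
  stopifnot(inherits(spec, "vx_phantom_spec"))
  if (!condition %in% spec$conditions)
    stop("condition '", condition, "' not in the spec's condition set")
  d <- spec$grid
  tmpl <- phantom_template(spec, condition)
  with_seed(seed, {
    img <- tmpl$image
    sup <- tmpl$support
    if (spec$deformation_amplitude > 0) {
      ux <- smooth_noise_field(d, spec$deformation_smoothness) *
        spec$deformation_amplitude
      uy <- smooth_noise_field(d, spec$deformation_smoothness) *
        spec$deformation_amplitude
      uz <- smooth_noise_field(d, spec$deformation_smoothness) *
        spec$deformation_amplitude
      co <- grid_coords(d)
      src <- co + cbind(as.numeric(ux), as.numeric(uy), as.numeric(uz))
      img <- array(sample_trilinear_cpp(as.numeric(img), as.integer(d), src,
                                        .vx_levels$background), dim = d)
      sup <- array(sample_trilinear_cpp(as.numeric(sup), as.integer(d), src,
                                        0) >= 0.5, dim = d)
    }
    if (spec$bias_amplitude > 0) {
      bias <- 1 + spec$bias_amplitude * smooth_noise_field(d, max(d) / 4)
      img <- img * bias
    }
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(prod(d), sd = spec$noise_sd)
    structure(list(id = paste0(condition, "_s", seed),
                   condition = condition,
                   image = vx_volume(img, spacing = spec$spacing),
                   true_mask = vx_mask(sup, spacing = spec$spacing)),
              class = "vx_subject")
  })
}

#' Generate a multi-condition phantom cohort
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' cohorts are reproducible and subjects are independent draws.
#'
#' @param spec a [phantom_spec()].
#' @param counts named integer vector: condition -> number of subjects
#'   (each >= 1; names must be in `spec$conditions`).
#' @param seed master seed.
#' @return A `vx_cohort`: list of `vx_subject`s with attributes `spec` and
#'   `seed`.
#' @export
generate_cohort <- function(spec, counts, seed) {
  stopifnot(inherits(spec, "vx_phantom_spec"), length(counts) >= 1,
            !is.null(names(counts)), all(counts >= 1))
  bad <- setdiff(names(counts), spec$conditions)
  if (length(bad))
    stop("counts name condition(s) outside the spec: ",
         paste(bad, collapse = ", "))
  subjects <- list()
  k <- 0L
  for (ci in seq_along(counts)) {
    cond <- names(counts)[ci]
    for (j in seq_len(counts[[ci]])) {
      k <- k + 1L
      # distinct, deterministic, and < 2^31
      sub_seed <- (seed * 1000L + ci * 100000L + j) %% .Machine$integer.max
      s <- generate_subject(spec, cond, sub_seed)
      s$id <- sprintf("%s_%02d", cond, j)
      subjects[[k]] <- s
    }
  }
  structure(subjects, class = "vx_cohort", spec = spec, seed = seed)
}

#' Write a cohort to disk with a CSV manifest
#'
#' @param cohort a `vx_cohort`.
#' @param dir output directory (created if missing).
#' @return Path to the manifest CSV (columns: subject_id, condition,
#'   image_path, mask_path).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vx_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    ip <- file.path(dir, paste0(s$id, "_image.nii.gz"))
    mp <- file.path(dir, paste0(s$id, "_mask.nii.gz"))
    write_volume(s$image, ip)
    write_mask(s$true_mask, mp)
    data.frame(subject_id = s$id, condition = s$condition,
               image_path = ip, mask_path = mp, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  mf
}

#' Read a cohort back from a manifest CSV
#'
#' @param manifest path to a manifest written by [write_cohort()] (columns
#'   subject_id, condition, image_path, mask_path; relative paths resolved
#'   against the manifest's directory).
#' @return A `vx_cohort`.
#' @export
read_cohort <- function(manifest) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "image_path", "mask_path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  subjects <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(id = df$subject_id[i], condition = df$condition[i],
                   image = read_volume(resolve(df$image_path[i])),
                   true_mask = read_mask(resolve(df$mask_path[i]))),
              class = "vx_subject")
  })
  structure(subjects, class = "vx_cohort")
}
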